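/* Planar Delaunay triangulation by incremental insertion (Bowyer-Watson).
 *
 * Plain O(n^2): every insertion scans all live triangles for circumcircles
 * containing the new point, carves out that cavity and re-fans it from the
 * point. Points exactly on a circumcircle (co-circular lattices) are counted
 * as inside, which keeps the cavity star-shaped in the degenerate case and
 * yields a valid (if arbitrary among equivalents) triangulation whose dual
 * Voronoi diagram is unaffected. Insertion order is a fixed pseudo-random
 * permutation so long collinear runs from lattice input do not stack up.
 * Circumcircles are computed in coordinates translated to the first vertex,
 * which keeps lattice circumcenters exact in double precision.
 */

#include <R.h>
#include <Rinternals.h>
#include <float.h>
#include <math.h>
#include <stdlib.h>
#include <string.h>

typedef struct {
    int v[3];
    double cx, cy, r2;
    int alive;
} tri_t;

static int circum(const double *x, const double *y, int a, int b, int c,
                  double *cx, double *cy, double *r2) {
    double bx = x[b] - x[a], by = y[b] - y[a];
    double cx_ = x[c] - x[a], cy_ = y[c] - y[a];
    double d = 2.0 * (bx * cy_ - by * cx_);
    double b2, c2, ux, uy;
    if (d == 0.0) return 0; /* collinear */
    b2 = bx * bx + by * by;
    c2 = cx_ * cx_ + cy_ * cy_;
    ux = (cy_ * b2 - by * c2) / d;
    uy = (bx * c2 - cx_ * b2) / d;
    *cx = ux + x[a];
    *cy = uy + y[a];
    *r2 = ux * ux + uy * uy;
    return 1;
}

SEXP C_delaunay(SEXP sx, SEXP sy) {
    int n = LENGTH(sx);
    int N = n + 3;
    double *x, *y;
    int maxtri, ntri = 0, nfree = 0;
    tri_t *tris;
    int *freelist, *order, *bad, *edges; /* edges: pairs */
    int i, j, k, t;
    double xmin = DBL_MAX, xmax = -DBL_MAX, ymin = DBL_MAX, ymax = -DBL_MAX;
    double cxm, cym, R;
    unsigned int rng = 123456789u;
    int degenerate = 0;

    if (n < 3) error("need at least 3 points for a triangulation");

    x = (double *)R_alloc((size_t)N, sizeof(double));
    y = (double *)R_alloc((size_t)N, sizeof(double));
    memcpy(x, REAL(sx), n * sizeof(double));
    memcpy(y, REAL(sy), n * sizeof(double));
    for (i = 0; i < n; i++) {
        if (!R_FINITE(x[i]) || !R_FINITE(y[i]))
            error("non-finite coordinate at point %d", i + 1);
        if (x[i] < xmin) xmin = x[i];
        if (x[i] > xmax) xmax = x[i];
        if (y[i] < ymin) ymin = y[i];
        if (y[i] > ymax) ymax = y[i];
    }
    cxm = 0.5 * (xmin + xmax);
    cym = 0.5 * (ymin + ymax);
    R = (xmax - xmin) + (ymax - ymin) + 1.0;
    /* big enclosing triangle; slightly irregular angles so the super vertices
       are not cocircular/collinear with grid-like data */
    x[n] = cxm + 60.0 * R * cos(0.17);
    y[n] = cym + 60.0 * R * sin(0.17);
    x[n + 1] = cxm + 63.0 * R * cos(2.31);
    y[n + 1] = cym + 63.0 * R * sin(2.31);
    x[n + 2] = cxm + 57.0 * R * cos(4.43);
    y[n + 2] = cym + 57.0 * R * sin(4.43);

    maxtri = 8 * N + 64;
    tris = (tri_t *)R_alloc((size_t)maxtri, sizeof(tri_t));
    freelist = (int *)R_alloc((size_t)maxtri, sizeof(int));
    order = (int *)R_alloc((size_t)n, sizeof(int));
    bad = (int *)R_alloc((size_t)maxtri, sizeof(int));
    edges = (int *)R_alloc((size_t)6 * maxtri, sizeof(int));

    tris[0].v[0] = n; tris[0].v[1] = n + 1; tris[0].v[2] = n + 2;
    if (!circum(x, y, n, n + 1, n + 2, &tris[0].cx, &tris[0].cy, &tris[0].r2))
        error("degenerate super-triangle");
    tris[0].alive = 1;
    ntri = 1;

    /* deterministic Fisher-Yates shuffle (fixed LCG) */
    for (i = 0; i < n; i++) order[i] = i;
    for (i = n - 1; i > 0; i--) {
        rng = rng * 1664525u + 1013904223u;
        j = (int)(rng % (unsigned int)(i + 1));
        t = order[i]; order[i] = order[j]; order[j] = t;
    }

    for (k = 0; k < n; k++) {
        int p = order[k];
        int nbad = 0, nedge = 0;
        double px = x[p], py = y[p];

        for (t = 0; t < ntri; t++) {
            double dx, dy, d2;
            if (!tris[t].alive) continue;
            dx = px - tris[t].cx;
            dy = py - tris[t].cy;
            d2 = dx * dx + dy * dy;
            /* on-circle counts as inside */
            if (d2 <= tris[t].r2 + 1e-9 * tris[t].r2) bad[nbad++] = t;
        }
        if (nbad == 0)
            error("point %d not inside any circumcircle (duplicate point?)",
                  p + 1);

        /* boundary = edges of the cavity that appear exactly once */
        for (i = 0; i < nbad; i++) {
            tri_t *tr = &tris[bad[i]];
            int e;
            for (e = 0; e < 3; e++) {
                int a = tr->v[e], b = tr->v[(e + 1) % 3];
                int lo = a < b ? a : b, hi = a < b ? b : a;
                int found = -1;
                for (j = 0; j < nedge; j++) {
                    if (edges[2 * j] == lo && edges[2 * j + 1] == hi) {
                        found = j;
                        break;
                    }
                }
                if (found >= 0) { /* interior edge: remove */
                    edges[2 * found] = edges[2 * (nedge - 1)];
                    edges[2 * found + 1] = edges[2 * (nedge - 1) + 1];
                    nedge--;
                } else {
                    edges[2 * nedge] = lo;
                    edges[2 * nedge + 1] = hi;
                    nedge++;
                }
            }
            tr->alive = 0;
            freelist[nfree++] = bad[i];
        }

        for (i = 0; i < nedge; i++) {
            int slot;
            int a = edges[2 * i], b = edges[2 * i + 1];
            double cx, cy, r2;
            if (!circum(x, y, p, a, b, &cx, &cy, &r2)) {
                /* collinear fan edge: make the sliver transient */
                cx = px; cy = py; r2 = DBL_MAX / 4.0;
                degenerate++;
            }
            if (nfree > 0)
                slot = freelist[--nfree];
            else {
                if (ntri == maxtri) error("triangle store overflow");
                slot = ntri++;
            }
            tris[slot].v[0] = p;
            tris[slot].v[1] = a;
            tris[slot].v[2] = b;
            tris[slot].cx = cx;
            tris[slot].cy = cy;
            tris[slot].r2 = r2;
            tris[slot].alive = 1;
        }
    }

    /* emit live triangles not touching the super-triangle */
    {
        int m = 0, r = 0;
        SEXP ans, nm, stri, scc, sr2;
        int *iv;
        double *dcc, *dr2;
        for (t = 0; t < ntri; t++)
            if (tris[t].alive && tris[t].v[0] < n && tris[t].v[1] < n &&
                tris[t].v[2] < n)
                m++;
        ans = PROTECT(allocVector(VECSXP, 4));
        stri = PROTECT(allocMatrix(INTSXP, m, 3));
        scc = PROTECT(allocMatrix(REALSXP, m, 2));
        sr2 = PROTECT(allocVector(REALSXP, m));
        iv = INTEGER(stri);
        dcc = REAL(scc);
        dr2 = REAL(sr2);
        for (t = 0; t < ntri; t++) {
            if (!tris[t].alive || tris[t].v[0] >= n || tris[t].v[1] >= n ||
                tris[t].v[2] >= n)
                continue;
            iv[r] = tris[t].v[0] + 1;
            iv[r + m] = tris[t].v[1] + 1;
            iv[r + 2 * m] = tris[t].v[2] + 1;
            dcc[r] = tris[t].cx;
            dcc[r + m] = tris[t].cy;
            dr2[r] = tris[t].r2;
            r++;
        }
        SET_VECTOR_ELT(ans, 0, stri);
        SET_VECTOR_ELT(ans, 1, scc);
        SET_VECTOR_ELT(ans, 2, sr2);
        SET_VECTOR_ELT(ans, 3, ScalarInteger(degenerate));
        nm = PROTECT(allocVector(STRSXP, 4));
        SET_STRING_ELT(nm, 0, mkChar("triangles"));
        SET_STRING_ELT(nm, 1, mkChar("circumcenters"));
        SET_STRING_ELT(nm, 2, mkChar("r2"));
        SET_STRING_ELT(nm, 3, mkChar("degenerate"));
        setAttrib(ans, R_NamesSymbol, nm);
        UNPROTECT(5);
        return ans;
    }
}
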