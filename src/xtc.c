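/* GROMACS XTC trajectory reader/writer.
 *
 * XTC is a big-endian XDR stream; each frame is a small header (magic 1995,
 * natoms, step, time, 3x3 box in nm) followed by a "3dfcoord" block holding
 * coordinates scaled by `precision`, rounded to integers and bit-packed.
 * Frames with <= 9 atoms store plain floats instead (and no precision field).
 * The integer coder is the classic Lindahl/Spoel scheme: per-frame min/max
 * integer bounds, a shared multi-radix big-integer packing for "large"
 * triplets and a run-length-coded small-delta mode whose radix adapts via the
 * magicints ladder. Implemented here from the format description; the bit
 * layout must match GROMACS exactly, which the test-suite cross-checks
 * against an independent reader.
 */

#include <R.h>
#include <Rinternals.h>
#include <limits.h>
#include <math.h>
#include <stdint.h>
#include <stdio.h>
#include <stdlib.h>
#include <string.h>

#define XTC_MAGIC 1995
#define MAXABS (INT_MAX - 2)

static const int magicints[] = {
    0,       0,       0,       0,       0,       0,       0,        0,
    0,       8,       10,      12,      16,      20,      25,       32,
    40,      50,      64,      80,      101,     128,     161,      203,
    256,     322,     406,     512,     645,     812,     1024,     1290,
    1625,    2048,    2580,    3250,    4096,    5060,    6501,     8192,
    10321,   13003,   16384,   20642,   26007,   32768,   41285,    52015,
    65536,   82570,   104031,  131072,  165140,  208063,  262144,   330280,
    416127,  524287,  660561,  832255,  1048576, 1321122, 1664510,  2097152,
    2642245, 3329021, 4194304, 5284491, 6658042, 8388607, 10568983, 13316085,
    16777216};
#define FIRSTIDX 9
#define LASTIDX ((int)(sizeof(magicints) / sizeof(*magicints)))

/* ---- raw big-endian primitives on FILE* ---- */

static int rd_u32(FILE *fp, uint32_t *out) {
    unsigned char b[4];
    if (fread(b, 1, 4, fp) != 4) return 0;
    *out = ((uint32_t)b[0] << 24) | ((uint32_t)b[1] << 16) |
           ((uint32_t)b[2] << 8) | (uint32_t)b[3];
    return 1;
}

static int rd_i32(FILE *fp, int32_t *out) {
    uint32_t u;
    if (!rd_u32(fp, &u)) return 0;
    *out = (int32_t)u;
    return 1;
}

static int rd_f32(FILE *fp, float *out) {
    union { uint32_t u; float f; } c;
    if (!rd_u32(fp, &c.u)) return 0;
    *out = c.f;
    return 1;
}

static void wr_u32(FILE *fp, uint32_t v) {
    unsigned char b[4];
    b[0] = (unsigned char)(v >> 24);
    b[1] = (unsigned char)(v >> 16);
    b[2] = (unsigned char)(v >> 8);
    b[3] = (unsigned char)v;
    fwrite(b, 1, 4, fp);
}

static void wr_i32(FILE *fp, int32_t v) { wr_u32(fp, (uint32_t)v); }

static void wr_f32(FILE *fp, float v) {
    union { uint32_t u; float f; } c;
    c.f = v;
    wr_u32(fp, c.u);
}

/* ---- bit buffer (first three ints are cursor state, bytes follow) ---- */

static void sendbits(int buf[], int num_of_bits, int num) {
    unsigned int cnt, lastbyte;
    int lastbits;
    unsigned char *cbuf = ((unsigned char *)buf) + 3 * sizeof(*buf);

    cnt = (unsigned int)buf[0];
    lastbits = buf[1];
    lastbyte = (unsigned int)buf[2];
    while (num_of_bits >= 8) {
        lastbyte = (lastbyte << 8) | (((unsigned int)num >> (num_of_bits - 8)) & 0xff);
        cbuf[cnt++] = (unsigned char)(lastbyte >> lastbits);
        num_of_bits -= 8;
    }
    if (num_of_bits > 0) {
        lastbyte = (lastbyte << num_of_bits) |
                   ((unsigned int)num & ((1u << num_of_bits) - 1));
        lastbits += num_of_bits;
        if (lastbits >= 8) {
            lastbits -= 8;
            cbuf[cnt++] = (unsigned char)(lastbyte >> lastbits);
        }
    }
    buf[0] = (int)cnt;
    buf[1] = lastbits;
    buf[2] = (int)lastbyte;
    if (lastbits > 0) cbuf[cnt] = (unsigned char)(lastbyte << (8 - lastbits));
}

static int receivebits(int buf[], int num_of_bits) {
    int cnt, num, lastbits;
    unsigned int lastbyte;
    unsigned char *cbuf = ((unsigned char *)buf) + 3 * sizeof(*buf);
    int mask = (1 << num_of_bits) - 1;

    cnt = buf[0];
    lastbits = buf[1];
    lastbyte = (unsigned int)buf[2];

    num = 0;
    while (num_of_bits >= 8) {
        lastbyte = (lastbyte << 8) | cbuf[cnt++];
        num |= (int)((lastbyte >> lastbits) << (num_of_bits - 8));
        num_of_bits -= 8;
    }
    if (num_of_bits > 0) {
        if (lastbits < num_of_bits) {
            lastbits += 8;
            lastbyte = (lastbyte << 8) | cbuf[cnt++];
        }
        lastbits -= num_of_bits;
        num |= (int)((lastbyte >> lastbits) & ((1u << num_of_bits) - 1));
    }
    num &= mask;
    buf[0] = cnt;
    buf[1] = lastbits;
    buf[2] = (int)lastbyte;
    return num;
}

static int sizeofint(int size) {
    int num = 1, num_of_bits = 0;
    while (size >= num && num_of_bits < 32) {
        num_of_bits++;
        num <<= 1;
    }
    return num_of_bits;
}

static int sizeofints(int num_of_ints, const unsigned int sizes[]) {
    int i, num;
    int bytes[32];
    unsigned int num_of_bytes, num_of_bits, bytecnt, tmp;

    num_of_bytes = 1;
    bytes[0] = 1;
    num_of_bits = 0;
    for (i = 0; i < num_of_ints; i++) {
        tmp = 0;
        for (bytecnt = 0; bytecnt < num_of_bytes; bytecnt++) {
            tmp = (unsigned int)bytes[bytecnt] * sizes[i] + tmp;
            bytes[bytecnt] = (int)(tmp & 0xff);
            tmp >>= 8;
        }
        while (tmp != 0) {
            bytes[bytecnt++] = (int)(tmp & 0xff);
            tmp >>= 8;
        }
        num_of_bytes = bytecnt;
    }
    num = 1;
    num_of_bytes--;
    while ((unsigned int)bytes[num_of_bytes] >= (unsigned int)num) {
        num_of_bits++;
        num *= 2;
    }
    return (int)(num_of_bits + num_of_bytes * 8);
}

static void sendints(int buf[], int num_of_ints, int num_of_bits,
                     const unsigned int sizes[], const unsigned int nums[]) {
    int i, num_of_bytes, bytecnt;
    unsigned int bytes[32], tmp;

    tmp = nums[0];
    num_of_bytes = 0;
    do {
        bytes[num_of_bytes++] = tmp & 0xff;
        tmp >>= 8;
    } while (tmp != 0);

    for (i = 1; i < num_of_ints; i++) {
        /* one-step multiply-accumulate in base 256 */
        tmp = nums[i];
        for (bytecnt = 0; bytecnt < num_of_bytes; bytecnt++) {
            tmp = bytes[bytecnt] * sizes[i] + tmp;
            bytes[bytecnt] = tmp & 0xff;
            tmp >>= 8;
        }
        while (tmp != 0) {
            bytes[bytecnt++] = tmp & 0xff;
            tmp >>= 8;
        }
        num_of_bytes = bytecnt;
    }
    if (num_of_bits >= num_of_bytes * 8) {
        for (i = 0; i < num_of_bytes; i++) sendbits(buf, 8, (int)bytes[i]);
        sendbits(buf, num_of_bits - num_of_bytes * 8, 0);
    } else {
        for (i = 0; i < num_of_bytes - 1; i++) sendbits(buf, 8, (int)bytes[i]);
        sendbits(buf, num_of_bits - (num_of_bytes - 1) * 8, (int)bytes[i]);
    }
}

static void receiveints(int buf[], int num_of_ints, int num_of_bits,
                        const unsigned int sizes[], int nums[]) {
    int bytes[32];
    int i, j, num_of_bytes, p, num;

    bytes[0] = bytes[1] = bytes[2] = bytes[3] = 0;
    num_of_bytes = 0;
    while (num_of_bits > 8) {
        bytes[num_of_bytes++] = receivebits(buf, 8);
        num_of_bits -= 8;
    }
    if (num_of_bits > 0) bytes[num_of_bytes++] = receivebits(buf, num_of_bits);
    for (i = num_of_ints - 1; i > 0; i--) {
        num = 0;
        for (j = num_of_bytes - 1; j >= 0; j--) {
            num = (num << 8) | bytes[j];
            p = num / (int)sizes[i];
            bytes[j] = p;
            num = num - p * (int)sizes[i];
        }
        nums[i] = num;
    }
    nums[0] = bytes[0] | (bytes[1] << 8) | (bytes[2] << 16) | (bytes[3] << 24);
}

/* ---- 3dfcoord compression ---- */

/* Encode natoms*3 floats (nm) into fp. Returns 0 on failure. */
static int xtc_write_coords(FILE *fp, const float *coords, int natoms,
                            float precision) {
    int size3 = natoms * 3;
    int i, k;
    int minint[3], maxint[3], sizeint[3], bitsizeint[3];
    unsigned int usizeint[3], sizesmall[3];
    int mindiff, oldl[3], l[3], diff;
    int bitsize, smallidx, maxidx, minidx, tmp;
    int smaller, smallnum, larger;
    int *ip, *buf;
    int prevcoord[3] = {0, 0, 0};
    unsigned int tmpcoord[30];
    int prevrun = -1, run = 0, is_small, is_smaller;
    double lf;

    wr_i32(fp, natoms);
    if (natoms <= 9) {
        for (i = 0; i < size3; i++) wr_f32(fp, coords[i]);
        return 1;
    }
    wr_f32(fp, precision);

    ip = (int *)R_alloc((size_t)size3, sizeof(int));
    buf = (int *)R_alloc((size_t)size3 * 2 + 256, sizeof(int));
    buf[0] = buf[1] = buf[2] = 0;

    minint[0] = minint[1] = minint[2] = INT_MAX;
    maxint[0] = maxint[1] = maxint[2] = INT_MIN;
    mindiff = INT_MAX;
    oldl[0] = oldl[1] = oldl[2] = 0;
    for (i = 0; i < natoms; i++) {
        for (k = 0; k < 3; k++) {
            lf = (double)coords[3 * i + k] * precision;
            lf += (lf >= 0.0) ? 0.5 : -0.5;
            if (fabs(lf) > MAXABS) return 0;
            l[k] = (int)lf;
            if (l[k] < minint[k]) minint[k] = l[k];
            if (l[k] > maxint[k]) maxint[k] = l[k];
            ip[3 * i + k] = l[k];
        }
        diff = abs(oldl[0] - l[0]) + abs(oldl[1] - l[1]) + abs(oldl[2] - l[2]);
        if (diff < mindiff && i > 0) mindiff = diff;
        oldl[0] = l[0];
        oldl[1] = l[1];
        oldl[2] = l[2];
    }
    for (k = 0; k < 3; k++) wr_i32(fp, minint[k]);
    for (k = 0; k < 3; k++) wr_i32(fp, maxint[k]);

    if ((double)maxint[0] - (double)minint[0] >= MAXABS ||
        (double)maxint[1] - (double)minint[1] >= MAXABS ||
        (double)maxint[2] - (double)minint[2] >= MAXABS)
        return 0;
    for (k = 0; k < 3; k++) {
        sizeint[k] = maxint[k] - minint[k] + 1;
        usizeint[k] = (unsigned int)sizeint[k];
    }
    if ((sizeint[0] | sizeint[1] | sizeint[2]) > 0xffffff) {
        bitsizeint[0] = sizeofint(sizeint[0]);
        bitsizeint[1] = sizeofint(sizeint[1]);
        bitsizeint[2] = sizeofint(sizeint[2]);
        bitsize = 0;
    } else {
        bitsize = sizeofints(3, usizeint);
    }

    smallidx = FIRSTIDX;
    while (smallidx < LASTIDX - 1 && magicints[smallidx] < mindiff) smallidx++;
    wr_i32(fp, smallidx);

    tmp = smallidx + 8;
    maxidx = (LASTIDX - 1 < tmp) ? LASTIDX - 1 : tmp;
    minidx = maxidx - 8;
    tmp = smallidx - 1;
    tmp = (FIRSTIDX > tmp) ? FIRSTIDX : tmp;
    smaller = magicints[tmp] / 2;
    smallnum = magicints[smallidx] / 2;
    sizesmall[0] = sizesmall[1] = sizesmall[2] = (unsigned int)magicints[smallidx];
    larger = magicints[maxidx] / 2;

    i = 0;
    while (i < natoms) {
        int *thiscoord = ip + (size_t)i * 3;

        is_small = 0;
        if (smallidx < maxidx && i >= 1 &&
            abs(thiscoord[0] - prevcoord[0]) < larger &&
            abs(thiscoord[1] - prevcoord[1]) < larger &&
            abs(thiscoord[2] - prevcoord[2]) < larger)
            is_smaller = 1;
        else if (smallidx > minidx)
            is_smaller = -1;
        else
            is_smaller = 0;
        if (i + 1 < natoms) {
            if (abs(thiscoord[0] - thiscoord[3]) < smallnum &&
                abs(thiscoord[1] - thiscoord[4]) < smallnum &&
                abs(thiscoord[2] - thiscoord[5]) < smallnum) {
                /* interchange atoms i and i+1: typically water O/H */
                tmp = thiscoord[0]; thiscoord[0] = thiscoord[3]; thiscoord[3] = tmp;
                tmp = thiscoord[1]; thiscoord[1] = thiscoord[4]; thiscoord[4] = tmp;
                tmp = thiscoord[2]; thiscoord[2] = thiscoord[5]; thiscoord[5] = tmp;
                is_small = 1;
            }
        }
        tmpcoord[0] = (unsigned int)(thiscoord[0] - minint[0]);
        tmpcoord[1] = (unsigned int)(thiscoord[1] - minint[1]);
        tmpcoord[2] = (unsigned int)(thiscoord[2] - minint[2]);
        if (bitsize == 0) {
            sendbits(buf, bitsizeint[0], (int)tmpcoord[0]);
            sendbits(buf, bitsizeint[1], (int)tmpcoord[1]);
            sendbits(buf, bitsizeint[2], (int)tmpcoord[2]);
        } else {
            sendints(buf, 3, bitsize, usizeint, tmpcoord);
        }
        prevcoord[0] = thiscoord[0];
        prevcoord[1] = thiscoord[1];
        prevcoord[2] = thiscoord[2];
        thiscoord += 3;
        i++;

        run = 0;
        if (is_small == 0 && is_smaller == -1) is_smaller = 0;
        while (is_small && run < 8 * 3) {
            if (is_smaller == -1 &&
                ((double)(thiscoord[0] - prevcoord[0]) * (thiscoord[0] - prevcoord[0]) +
                     (double)(thiscoord[1] - prevcoord[1]) * (thiscoord[1] - prevcoord[1]) +
                     (double)(thiscoord[2] - prevcoord[2]) * (thiscoord[2] - prevcoord[2]) >=
                 (double)smaller * smaller))
                is_smaller = 0;

            tmpcoord[run++] = (unsigned int)(thiscoord[0] - prevcoord[0] + smallnum);
            tmpcoord[run++] = (unsigned int)(thiscoord[1] - prevcoord[1] + smallnum);
            tmpcoord[run++] = (unsigned int)(thiscoord[2] - prevcoord[2] + smallnum);

            prevcoord[0] = thiscoord[0];
            prevcoord[1] = thiscoord[1];
            prevcoord[2] = thiscoord[2];

            i++;
            thiscoord += 3;
            is_small = 0;
            if (i < natoms && abs(thiscoord[0] - prevcoord[0]) < smallnum &&
                abs(thiscoord[1] - prevcoord[1]) < smallnum &&
                abs(thiscoord[2] - prevcoord[2]) < smallnum)
                is_small = 1;
        }
        if (run != prevrun || is_smaller != 0) {
            prevrun = run;
            sendbits(buf, 1, 1);
            sendbits(buf, 5, run + is_smaller + 1);
        } else {
            sendbits(buf, 1, 0);
        }
        for (k = 0; k < run; k += 3)
            sendints(buf, 3, smallidx, sizesmall, &tmpcoord[k]);
        if (is_smaller != 0) {
            smallidx += is_smaller;
            if (is_smaller < 0) {
                smallnum = smaller;
                smaller = magicints[smallidx - 1] / 2;
            } else {
                smaller = smallnum;
                smallnum = magicints[smallidx] / 2;
            }
            sizesmall[0] = sizesmall[1] = sizesmall[2] = (unsigned int)magicints[smallidx];
        }
    }
    if (buf[1] != 0) buf[0]++;
    wr_i32(fp, buf[0]); /* compressed byte count */
    {
        unsigned char *cbuf = ((unsigned char *)buf) + 3 * sizeof(*buf);
        int nb = buf[0];
        int pad = (4 - nb % 4) % 4;
        fwrite(cbuf, 1, (size_t)nb, fp);
        for (k = 0; k < pad; k++) fputc(0, fp);
    }
    return 1;
}

/* Decode one compressed coordinate block; coords must hold natoms*3 floats. */
static int xtc_read_coords(FILE *fp, float *coords, int natoms,
                           float *precision) {
    int32_t lsize;
    int size3, i, k, run = 0;
    int minint[3], maxint[3], sizeint[3], bitsizeint[3];
    unsigned int usizeint[3], sizesmall[3];
    int bitsize, smallidx, tmp;
    int smaller, smallnum;
    int32_t nbytes;
    int *buf;
    int thiscoord[3], prevcoord[3] = {0, 0, 0}, tcoord[3];
    int flag, is_smaller;
    float inv_precision;

    if (!rd_i32(fp, &lsize)) return 0;
    if (lsize != natoms) return -1;
    size3 = natoms * 3;
    if (natoms <= 9) {
        *precision = -1.0f;
        for (i = 0; i < size3; i++)
            if (!rd_f32(fp, &coords[i])) return 0;
        return 1;
    }
    if (!rd_f32(fp, precision)) return 0;
    inv_precision = 1.0f / *precision;

    for (k = 0; k < 3; k++) if (!rd_i32(fp, (int32_t *)&minint[k])) return 0;
    for (k = 0; k < 3; k++) if (!rd_i32(fp, (int32_t *)&maxint[k])) return 0;
    for (k = 0; k < 3; k++) {
        sizeint[k] = maxint[k] - minint[k] + 1;
        usizeint[k] = (unsigned int)sizeint[k];
    }
    if ((sizeint[0] | sizeint[1] | sizeint[2]) > 0xffffff) {
        bitsizeint[0] = sizeofint(sizeint[0]);
        bitsizeint[1] = sizeofint(sizeint[1]);
        bitsizeint[2] = sizeofint(sizeint[2]);
        bitsize = 0;
    } else {
        bitsize = sizeofints(3, usizeint);
    }
    if (!rd_i32(fp, (int32_t *)&smallidx)) return 0;
    if (smallidx < FIRSTIDX || smallidx >= LASTIDX) return -1;

    tmp = smallidx - 1;
    tmp = (FIRSTIDX > tmp) ? FIRSTIDX : tmp;
    smaller = magicints[tmp] / 2;
    smallnum = magicints[smallidx] / 2;
    sizesmall[0] = sizesmall[1] = sizesmall[2] = (unsigned int)magicints[smallidx];

    if (!rd_i32(fp, &nbytes)) return 0;
    if (nbytes < 0 || nbytes > size3 * 8 + 1024) return -1;
    buf = (int *)R_alloc((size_t)size3 * 2 + 256, sizeof(int));
    {
        unsigned char *cbuf = ((unsigned char *)buf) + 3 * sizeof(*buf);
        int nb = (int)nbytes, pad = (4 - nb % 4) % 4;
        if (fread(cbuf, 1, (size_t)(nb + pad), fp) != (size_t)(nb + pad)) return 0;
    }
    buf[0] = buf[1] = buf[2] = 0;

    i = 0;
    {
        float *lfp = coords;
        while (i < natoms) {
            if (bitsize == 0) {
                thiscoord[0] = receivebits(buf, bitsizeint[0]);
                thiscoord[1] = receivebits(buf, bitsizeint[1]);
                thiscoord[2] = receivebits(buf, bitsizeint[2]);
            } else {
                receiveints(buf, 3, bitsize, usizeint, thiscoord);
            }
            i++;
            thiscoord[0] += minint[0];
            thiscoord[1] += minint[1];
            thiscoord[2] += minint[2];
            prevcoord[0] = thiscoord[0];
            prevcoord[1] = thiscoord[1];
            prevcoord[2] = thiscoord[2];

            flag = receivebits(buf, 1);
            is_smaller = 0;
            if (flag == 1) {
                run = receivebits(buf, 5);
                is_smaller = run % 3;
                run -= is_smaller;
                is_smaller--;
            }
            if (run > 0) {
                for (k = 0; k < run; k += 3) {
                    receiveints(buf, 3, smallidx, sizesmall, tcoord);
                    i++;
                    tcoord[0] += prevcoord[0] - smallnum;
                    tcoord[1] += prevcoord[1] - smallnum;
                    tcoord[2] += prevcoord[2] - smallnum;
                    if (k == 0) {
                        /* undo the encoder's pair interchange */
                        tmp = tcoord[0]; tcoord[0] = prevcoord[0]; prevcoord[0] = tmp;
                        tmp = tcoord[1]; tcoord[1] = prevcoord[1]; prevcoord[1] = tmp;
                        tmp = tcoord[2]; tcoord[2] = prevcoord[2]; prevcoord[2] = tmp;
                        *lfp++ = (float)prevcoord[0] * inv_precision;
                        *lfp++ = (float)prevcoord[1] * inv_precision;
                        *lfp++ = (float)prevcoord[2] * inv_precision;
                    } else {
                        prevcoord[0] = tcoord[0];
                        prevcoord[1] = tcoord[1];
                        prevcoord[2] = tcoord[2];
                    }
                    *lfp++ = (float)tcoord[0] * inv_precision;
                    *lfp++ = (float)tcoord[1] * inv_precision;
                    *lfp++ = (float)tcoord[2] * inv_precision;
                }
            } else {
                *lfp++ = (float)thiscoord[0] * inv_precision;
                *lfp++ = (float)thiscoord[1] * inv_precision;
                *lfp++ = (float)thiscoord[2] * inv_precision;
            }
            smallidx += is_smaller;
            if (is_smaller < 0) {
                smallnum = smaller;
                smaller = (smallidx > FIRSTIDX) ? magicints[smallidx - 1] / 2 : 0;
            } else if (is_smaller > 0) {
                smaller = smallnum;
                smallnum = magicints[smallidx] / 2;
            }
            sizesmall[0] = sizesmall[1] = sizesmall[2] = (unsigned int)magicints[smallidx];
        }
    }
    return 1;
}

/* Skip one coordinate block without decoding. Returns 1 ok, 0 eof/short. */
static int xtc_skip_coords(FILE *fp, int natoms) {
    int32_t lsize, nbytes;
    if (!rd_i32(fp, &lsize)) return 0;
    if (lsize <= 9) return fseek(fp, (long)lsize * 12, SEEK_CUR) == 0;
    /* precision + minint + maxint + smallidx */
    if (fseek(fp, 4 + 12 + 12 + 4, SEEK_CUR) != 0) return 0;
    if (!rd_i32(fp, &nbytes)) return 0;
    return fseek(fp, nbytes + ((4 - nbytes % 4) % 4), SEEK_CUR) == 0;
}

/* ---- .Call interface ---- */

/* Scan frame headers: returns list(natoms, step, time, offset). */
SEXP C_xtc_scan(SEXP spath) {
    const char *path = CHAR(STRING_ELT(spath, 0));
    FILE *fp = fopen(path, "rb");
    int cap = 256, n = 0, k;
    int32_t magic, natoms0 = -1, natoms, step;
    float t, boxv;
    double *steps, *times, *offs;
    SEXP ans, nm;

    if (!fp) error("cannot open '%s'", path);
    steps = (double *)R_alloc(cap, sizeof(double));
    times = (double *)R_alloc(cap, sizeof(double));
    offs = (double *)R_alloc(cap, sizeof(double));
    for (;;) {
        long at = ftell(fp);
        if (!rd_i32(fp, &magic)) break;
        if (magic != XTC_MAGIC) {
            fclose(fp);
            error("bad XTC magic at byte %ld in '%s'", at, path);
        }
        if (!rd_i32(fp, &natoms) || !rd_i32(fp, &step) || !rd_f32(fp, &t)) {
            fclose(fp);
            error("truncated XTC header in '%s'", path);
        }
        if (natoms0 < 0) natoms0 = natoms;
        else if (natoms != natoms0) {
            fclose(fp);
            error("inconsistent atom count in '%s'", path);
        }
        for (k = 0; k < 9; k++)
            if (!rd_f32(fp, &boxv)) { fclose(fp); error("truncated XTC box"); }
        if (n == cap) {
            double *s2 = (double *)R_alloc(cap * 2, sizeof(double));
            double *t2 = (double *)R_alloc(cap * 2, sizeof(double));
            double *o2 = (double *)R_alloc(cap * 2, sizeof(double));
            memcpy(s2, steps, n * sizeof(double));
            memcpy(t2, times, n * sizeof(double));
            memcpy(o2, offs, n * sizeof(double));
            steps = s2; times = t2; offs = o2;
            cap *= 2;
        }
        steps[n] = step;
        times[n] = t;
        offs[n] = (double)at;
        n++;
        if (!xtc_skip_coords(fp, natoms)) {
            fclose(fp);
            warning("truncated final XTC frame in '%s' ignored", path);
            n--;
            break;
        }
    }
    fclose(fp);

    ans = PROTECT(allocVector(VECSXP, 4));
    SET_VECTOR_ELT(ans, 0, ScalarInteger(natoms0 < 0 ? 0 : natoms0));
    SET_VECTOR_ELT(ans, 1, allocVector(REALSXP, n));
    SET_VECTOR_ELT(ans, 2, allocVector(REALSXP, n));
    SET_VECTOR_ELT(ans, 3, allocVector(REALSXP, n));
    memcpy(REAL(VECTOR_ELT(ans, 1)), steps, n * sizeof(double));
    memcpy(REAL(VECTOR_ELT(ans, 2)), times, n * sizeof(double));
    memcpy(REAL(VECTOR_ELT(ans, 3)), offs, n * sizeof(double));
    nm = PROTECT(allocVector(STRSXP, 4));
    SET_STRING_ELT(nm, 0, mkChar("natoms"));
    SET_STRING_ELT(nm, 1, mkChar("step"));
    SET_STRING_ELT(nm, 2, mkChar("time"));
    SET_STRING_ELT(nm, 3, mkChar("offset"));
    setAttrib(ans, R_NamesSymbol, nm);
    UNPROTECT(2);
    return ans;
}

/* Read one frame at a byte offset: list(natoms, step, time, box, coords). */
SEXP C_xtc_read_frame(SEXP spath, SEXP soffset) {
    const char *path = CHAR(STRING_ELT(spath, 0));
    FILE *fp = fopen(path, "rb");
    int32_t magic, natoms, step;
    float t, prec;
    float box[9], *coords;
    double *d;
    int k, ok;
    SEXP ans, nm, sbox, scoord;

    if (!fp) error("cannot open '%s'", path);
    if (fseek(fp, (long)REAL(soffset)[0], SEEK_SET) != 0) {
        fclose(fp);
        error("seek failed in '%s'", path);
    }
    if (!rd_i32(fp, &magic) || magic != XTC_MAGIC || !rd_i32(fp, &natoms) ||
        !rd_i32(fp, &step) || !rd_f32(fp, &t)) {
        fclose(fp);
        error("bad XTC frame header in '%s'", path);
    }
    for (k = 0; k < 9; k++)
        if (!rd_f32(fp, &box[k])) { fclose(fp); error("truncated XTC box"); }
    coords = (float *)R_alloc((size_t)natoms * 3, sizeof(float));
    ok = xtc_read_coords(fp, coords, natoms, &prec);
    fclose(fp);
    if (ok == 0) error("truncated XTC frame in '%s'", path);
    if (ok < 0) error("corrupt XTC coordinate block in '%s'", path);

    ans = PROTECT(allocVector(VECSXP, 6));
    SET_VECTOR_ELT(ans, 0, ScalarInteger(natoms));
    SET_VECTOR_ELT(ans, 1, ScalarInteger(step));
    SET_VECTOR_ELT(ans, 2, ScalarReal((double)t));
    sbox = PROTECT(allocVector(REALSXP, 9));
    for (k = 0; k < 9; k++) REAL(sbox)[k] = (double)box[k];
    SET_VECTOR_ELT(ans, 3, sbox);
    scoord = PROTECT(allocMatrix(REALSXP, natoms, 3));
    d = REAL(scoord);
    for (k = 0; k < natoms; k++) {
        d[k] = (double)coords[3 * k];
        d[k + natoms] = (double)coords[3 * k + 1];
        d[k + 2 * natoms] = (double)coords[3 * k + 2];
    }
    SET_VECTOR_ELT(ans, 4, scoord);
    SET_VECTOR_ELT(ans, 5, ScalarReal((double)prec));
    nm = PROTECT(allocVector(STRSXP, 6));
    SET_STRING_ELT(nm, 0, mkChar("natoms"));
    SET_STRING_ELT(nm, 1, mkChar("step"));
    SET_STRING_ELT(nm, 2, mkChar("time"));
    SET_STRING_ELT(nm, 3, mkChar("box"));
    SET_STRING_ELT(nm, 4, mkChar("coords"));
    SET_STRING_ELT(nm, 5, mkChar("precision"));
    setAttrib(ans, R_NamesSymbol, nm);
    UNPROTECT(4);
    return ans;
}

/* Append one frame. coords: natoms x 3 matrix (nm), box: 9 values row-major.*/
SEXP C_xtc_write_frame(SEXP spath, SEXP scoords, SEXP sbox, SEXP sstep,
                       SEXP stime, SEXP sprec, SEXP sappend) {
    const char *path = CHAR(STRING_ELT(spath, 0));
    FILE *fp = fopen(path, LOGICAL(sappend)[0] ? "ab" : "wb");
    int natoms = nrows(scoords);
    int k;
    float *coords;
    double *d = REAL(scoords);

    if (!fp) error("cannot open '%s' for writing", path);
    wr_i32(fp, XTC_MAGIC);
    wr_i32(fp, natoms);
    wr_i32(fp, INTEGER(sstep)[0]);
    wr_f32(fp, (float)REAL(stime)[0]);
    for (k = 0; k < 9; k++) wr_f32(fp, (float)REAL(sbox)[k]);
    coords = (float *)R_alloc((size_t)natoms * 3, sizeof(float));
    for (k = 0; k < natoms; k++) {
        coords[3 * k] = (float)d[k];
        coords[3 * k + 1] = (float)d[k + natoms];
        coords[3 * k + 2] = (float)d[k + 2 * natoms];
    }
    if (!xtc_write_coords(fp, coords, natoms, (float)REAL(sprec)[0])) {
        fclose(fp);
        error("coordinates too large for XTC integer coding");
    }
    fclose(fp);
    return R_NilValue;
}
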