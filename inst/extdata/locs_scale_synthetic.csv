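t,r,g,b
0.00000000,0,0,0
0.00392157,0,0,9
0.00784314,0,0,18
0.01176471,0,0,26
0.01568627,0,0,35
0.01960784,0,0,44
0.02352941,0,0,53
0.02745098,0,0,61
0.03137255,0,0,70
0.03529412,0,0,79
0.03921569,0,0,88
0.04313725,0,0,96
0.04705882,0,0,105
0.05098039,0,0,114
0.05490196,0,0,123
0.05882353,0,0,132
0.06274510,0,0,140
0.06666667,0,0,149
0.07058824,0,0,158
0.07450980,0,0,167
0.07843137,0,0,175
0.08235294,0,0,184
0.08627451,0,0,193
0.09019608,0,0,202
0.09411765,0,0,211
0.09803922,0,0,219
0.10196078,0,0,228
0.10588235,0,0,237
0.10980392,0,0,246
0.11372549,0,0,254
0.11764706,3,0,255
0.12156863,6,0,255
0.12549020,10,0,255
0.12941176,13,0,255
0.13333333,16,0,255
0.13725490,20,0,255
0.14117647,23,0,255
0.14509804,27,0,255
0.14901961,30,0,255
0.15294118,33,0,255
0.15686275,37,0,255
0.16078431,40,0,255
0.16470588,43,0,255
0.16862745,47,0,255
0.17254902,50,0,255
0.17647059,53,0,255
0.18039216,57,0,255
0.18431373,60,0,255
0.18823529,63,0,255
0.19215686,67,0,255
0.19607843,70,0,255
0.20000000,73,0,255
0.20392157,77,0,255
0.20784314,80,0,255
0.21176471,83,0,255
0.21568627,87,0,255
0.21960784,90,0,255
0.22352941,93,0,255
0.22745098,97,0,255
0.23137255,100,0,255
0.23529412,103,0,255
0.23921569,107,0,255
0.24313725,110,0,255
0.24705882,113,0,255
0.25098039,117,0,255
0.25490196,120,0,255
0.25882353,124,0,255
0.26274510,127,0,255
0.26666667,130,0,255
0.27058824,134,0,255
0.27450980,137,0,255
0.27843137,140,0,255
0.28235294,144,0,255
0.28627451,147,0,255
0.29019608,150,0,255
0.29411765,154,0,255
0.29803922,157,0,255
0.30196078,160,0,255
0.30588235,164,0,255
0.30980392,167,0,255
0.31372549,170,0,255
0.31764706,174,0,255
0.32156863,177,0,255
0.32549020,180,0,255
0.32941176,184,0,255
0.33333333,187,0,255
0.33725490,190,0,255
0.34117647,194,0,255
0.34509804,197,0,255
0.34901961,200,0,255
0.35294118,204,0,255
0.35686275,207,0,255
0.36078431,210,0,255
0.36470588,214,0,255
0.36862745,217,0,255
0.37254902,221,0,255
0.37647059,224,0,255
0.38039216,227,0,255
0.38431373,231,0,255
0.38823529,234,0,255
0.39215686,237,0,255
0.39607843,241,0,255
0.40000000,244,0,255
0.40392157,247,0,255
0.40784314,251,0,255
0.41176471,254,0,255
0.41568627,255,2,251
0.41960784,255,5,246
0.42352941,255,7,240
0.42745098,255,10,234
0.43137255,255,13,229
0.43529412,255,16,223
0.43921569,255,19,218
0.44313725,255,21,212
0.44705882,255,24,207
0.45098039,255,27,201
0.45490196,255,30,195
0.45882353,255,33,190
0.46274510,255,35,184
0.46666667,255,38,179
0.47058824,255,41,173
0.47450980,255,44,168
0.47843137,255,46,162
0.48235294,255,49,156
0.48627451,255,52,151
0.49019608,255,55,145
0.49411765,255,58,140
0.49803922,255,60,134
0.50196078,255,63,129
0.50588235,255,66,123
0.50980392,255,69,117
0.51372549,255,72,112
0.51764706,255,74,106
0.52156863,255,77,101
0.52549020,255,80,95
0.52941176,255,83,90
0.53333333,255,85,84
0.53725490,255,88,78
0.54117647,255,91,73
0.54509804,255,94,67
0.54901961,255,97,62
0.55294118,255,99,56
0.55686275,255,102,51
0.56078431,255,105,45
0.56470588,255,108,39
0.56862745,255,111,34
0.57254902,255,113,28
0.57647059,255,116,23
0.58039216,255,119,17
0.58431373,255,122,12
0.58823529,255,124,6
0.59215686,255,127,0
0.59607843,255,129,0
0.60000000,255,131,0
0.60392157,255,132,0
0.60784314,255,134,0
0.61176471,255,136,0
0.61568627,255,138,0
0.61960784,255,139,0
0.62352941,255,141,0
0.62745098,255,143,0
0.63137255,255,144,0
0.63529412,255,146,0
0.63921569,255,148,0
0.64313725,255,149,0
0.64705882,255,151,0
0.65098039,255,153,0
0.65490196,255,155,0
0.65882353,255,156,0
0.66274510,255,158,0
0.66666667,255,160,0
0.67058824,255,161,0
0.67450980,255,163,0
0.67843137,255,165,0
0.68235294,255,167,0
0.68627451,255,168,0
0.69019608,255,170,0
0.69411765,255,172,0
0.69803922,255,173,0
0.70196078,255,175,0
0.70588235,255,177,0
0.70980392,255,178,0
0.71372549,255,180,0
0.71764706,255,182,0
0.72156863,255,184,0
0.72549020,255,185,0
0.72941176,255,187,0
0.73333333,255,189,0
0.73725490,255,190,0
0.74117647,255,192,0
0.74509804,255,194,0
0.74901961,255,195,0
0.75294118,255,197,0
0.75686275,255,199,0
0.76078431,255,201,0
0.76470588,255,202,0
0.76862745,255,204,0
0.77254902,255,206,0
0.77647059,255,207,0
0.78039216,255,209,0
0.78431373,255,211,0
0.78823529,255,213,0
0.79215686,255,214,0
0.79607843,255,216,0
0.80000000,255,218,0
0.80392157,255,219,0
0.80784314,255,221,0
0.81176471,255,223,0
0.81568627,255,224,0
0.81960784,255,226,0
0.82352941,255,228,0
0.82745098,255,230,0
0.83137255,255,231,0
0.83529412,255,233,0
0.83921569,255,235,0
0.84313725,255,236,0
0.84705882,255,238,0
0.85098039,255,240,0
0.85490196,255,241,0
0.85882353,255,243,0
0.86274510,255,245,0
0.86666667,255,247,0
0.87058824,255,248,0
0.87450980,255,250,0
0.87843137,255,252,0
0.88235294,255,253,0
0.88627451,255,255,1
0.89019608,255,255,9
0.89411765,255,255,18
0.89803922,255,255,27
0.90196078,255,255,36
0.90588235,255,255,44
0.90980392,255,255,53
0.91372549,255,255,62
0.91764706,255,255,71
0.92156863,255,255,80
0.92549020,255,255,88
0.92941176,255,255,97
0.93333333,255,255,106
0.93725490,255,255,115
0.94117647,255,255,123
0.94509804,255,255,132
0.94901961,255,255,141
0.95294118,255,255,150
0.95686275,255,255,159
0.96078431,255,255,167
0.96470588,255,255,176
0.96862745,255,255,185
0.97254902,255,255,194
0.97647059,255,255,202
0.98039216,255,255,211
0.98431373,255,255,220
0.98823529,255,255,229
0.99215686,255,255,237
0.99607843,255,255,246
1.00000000,255,255,255
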