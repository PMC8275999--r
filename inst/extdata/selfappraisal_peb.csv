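contrast,source,target,pe,pp
group_mean,AIns,AIns,0.37,0.99
group_mean,AIns,DLPFC,-0.028,0.71
group_mean,AIns,MPFC,-0.050,0.82
group_mean,AIns,PCC,-0.071,0.90
group_mean,AIns,TPJ,-0.012,0.60
group_mean,AIns,lPG,-0.012,0.60
group_mean,AIns,rPG,-0.29,1
group_mean,DLPFC,DLPFC,-0.044,0.78
group_mean,DLPFC,AIns,0.055,0.85
group_mean,DLPFC,MPFC,-0.030,0.71
group_mean,DLPFC,PCC,0.049,0.85
group_mean,DLPFC,TPJ,0.010,0.58
group_mean,DLPFC,lPG,0.050,0.85
group_mean,DLPFC,rPG,0.050,0.84
group_mean,MPFC,MPFC,0.52,1
group_mean,MPFC,AIns,0.060,0.87
group_mean,MPFC,DLPFC,-0.011,0.58
group_mean,MPFC,PCC,0.042,0.78
group_mean,MPFC,TPJ,0.035,0.75
group_mean,MPFC,lPG,-0.035,0.74
group_mean,MPFC,rPG,0.015,0.62
group_mean,PCC,PCC,0.54,1
group_mean,PCC,AIns,-0.51,1
group_mean,PCC,DLPFC,-0.028,0.69
group_mean,PCC,MPFC,-0.019,0.64
group_mean,PCC,TPJ,0.022,0.67
group_mean,PCC,lPG,-0.019,0.65
group_mean,PCC,rPG,0.004,0.53
group_mean,TPJ,TPJ,-0.715,1
group_mean,TPJ,AIns,0.197,0.89
group_mean,TPJ,DLPFC,0.201,0.87
group_mean,TPJ,MPFC,0.604,1
group_mean,TPJ,PCC,-0.037,0.74
group_mean,TPJ,lPG,0.034,0.73
group_mean,TPJ,rPG,0.045,0.74
pos_vs_others,AIns,AIns,0.82,1
pos_vs_others,AIns,DLPFC,0.002,0.51
pos_vs_others,AIns,MPFC,-0.052,0.68
pos_vs_others,AIns,PCC,-0.058,0.71
pos_vs_others,AIns,TPJ,0.032,0.62
pos_vs_others,AIns,lPG,0.041,0.67
pos_vs_others,AIns,rPG,0.030,0.62
pos_vs_others,DLPFC,DLPFC,1.033,1
pos_vs_others,DLPFC,AIns,0.037,0.63
pos_vs_others,DLPFC,MPFC,0.036,0.62
pos_vs_others,DLPFC,PCC,0.073,0.76
pos_vs_others,DLPFC,TPJ,0.078,0.77
pos_vs_others,DLPFC,lPG,-0.035,0.65
pos_vs_others,DLPFC,rPG,0.001,0.50
pos_vs_others,MPFC,MPFC,0.070,0.71
pos_vs_others,MPFC,AIns,-0.829,1
pos_vs_others,MPFC,DLPFC,0.048,0.66
pos_vs_others,MPFC,PCC,-0.068,0.72
pos_vs_others,MPFC,TPJ,0.976,1
pos_vs_others,MPFC,lPG,-0.013,0.55
pos_vs_others,MPFC,rPG,-0.028,0.60
pos_vs_others,PCC,PCC,-1.281,1
pos_vs_others,PCC,AIns,-0.078,0.75
pos_vs_others,PCC,DLPFC,-0.050,0.66
pos_vs_others,PCC,MPFC,-0.062,0.70
pos_vs_others,PCC,TPJ,-0.070,0.74
pos_vs_others,PCC,lPG,0.070,0.73
pos_vs_others,PCC,rPG,0.086,0.74
pos_vs_others,TPJ,TPJ,-0.019,0.56
pos_vs_others,TPJ,AIns,-0.070,0.72
pos_vs_others,TPJ,DLPFC,-0.030,0.60
pos_vs_others,TPJ,MPFC,1.315,1
pos_vs_others,TPJ,PCC,0.655,0.99
pos_vs_others,TPJ,lPG,0.474,0.95
pos_vs_others,TPJ,rPG,-0.033,0.61
neg_vs_others,AIns,AIns,-0.096,0.78
neg_vs_others,AIns,DLPFC,-0.365,0.94
neg_vs_others,AIns,MPFC,0.001,0.50
neg_vs_others,AIns,PCC,0.024,0.58
neg_vs_others,AIns,TPJ,-0.068,0.75
neg_vs_others,AIns,lPG,-0.087,0.82
neg_vs_others,AIns,rPG,0.002,0.51
neg_vs_others,DLPFC,DLPFC,-1.328,1
neg_vs_others,DLPFC,AIns,-0.019,0.56
neg_vs_others,DLPFC,MPFC,-0.430,0.95
neg_vs_others,DLPFC,PCC,-0.358,0.97
neg_vs_others,DLPFC,TPJ,0.029,0.61
neg_vs_others,DLPFC,lPG,-0.014,0.56
neg_vs_others,DLPFC,rPG,-0.08,0.74
neg_vs_others,MPFC,MPFC,-0.058,0.68
neg_vs_others,MPFC,AIns,0.088,0.76
neg_vs_others,MPFC,DLPFC,0.013,0.54
neg_vs_others,MPFC,PCC,0.035,0.62
neg_vs_others,MPFC,TPJ,-0.148,0.89
neg_vs_others,MPFC,lPG,0.014,0.55
neg_vs_others,MPFC,rPG,-0.041,0.64
neg_vs_others,PCC,PCC,1.244,1
neg_vs_others,PCC,AIns,0.406,0.90
neg_vs_others,PCC,DLPFC,-0.028,0.59
neg_vs_others,PCC,MPFC,-0.032,0.61
neg_vs_others,PCC,TPJ,0.151,0.91
neg_vs_others,PCC,lPG,-0.052,0.67
neg_vs_others,PCC,rPG,-0.08,0.74
neg_vs_others,TPJ,TPJ,-0.083,0.75
neg_vs_others,TPJ,AIns,-0.045,0.64
neg_vs_others,TPJ,DLPFC,0.048,0.65
neg_vs_others,TPJ,MPFC,-0.787,1
neg_vs_others,TPJ,PCC,-0.107,0.82
neg_vs_others,TPJ,lPG,-0.015,0.55
neg_vs_others,TPJ,rPG,0.034,0.61
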