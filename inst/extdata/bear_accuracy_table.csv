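region,model,auc,boyce,tss,sensitivity,specificity
Big Bend,maxent,0.92,0.97,0.86,0.93,0.93
Big Bend,mahalanobis,0.95,0.95,0.76,0.83,0.94
Central,maxent,0.80,0.99,0.46,0.80,0.65
Central,mahalanobis,0.82,0.98,0.46,0.66,0.80
Eastern Panhandle,maxent,0.84,0.98,0.56,0.81,0.76
Eastern Panhandle,mahalanobis,0.93,0.99,0.67,0.76,0.91
North,maxent,0.84,0.98,0.83,0.96,0.87
North,mahalanobis,0.93,0.99,0.78,0.83,0.95
South Central,maxent,0.87,0.98,0.83,0.95,0.88
South Central,mahalanobis,0.93,0.99,0.70,0.79,0.91
South,maxent,0.82,0.99,0.78,0.91,0.86
South,mahalanobis,0.90,0.98,0.62,0.74,0.88
Western Panhandle,maxent,0.91,0.95,0.76,0.93,0.83
Western Panhandle,mahalanobis,0.86,0.90,0.57,0.82,0.75
State,maxent,0.76,1.00,0.36,0.79,0.57
State,mahalanobis,0.71,0.99,0.31,0.76,0.55
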