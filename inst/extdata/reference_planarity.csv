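sample,p0_um,px,py,mean_norm_dist,median_norm_dist,max_norm_dist
1,812.76,-0.006266,-0.01693,0.2071,0.1805,0.6915
2,888.18,-0.00760,-0.01678,0.3508,0.2762,1.1007
3,799.91,-0.011548,-0.00528,0.2306,0.2053,0.6558
4,512.34,-9.09E-05,-0.01062,0.2813,0.2218,1.2853
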