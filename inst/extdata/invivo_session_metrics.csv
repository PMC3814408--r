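experiment,level,mad,mdape,mdpe
1,low,0.027,5.43,-0.80
2,low,0.043,10.72,10.72
3,low,0.017,4.90,1.79
4,low,0.032,11.44,-11.44
5,low,0.034,8.47,-8.47
6,low,0.031,6.18,-3.04
1,mid,0.018,2.62,1.75
2,mid,0.016,2.32,1.00
3,mid,0.019,3.80,-0.40
4,mid,0.017,3.35,-1.45
5,mid,0.052,7.37,-7.37
6,mid,0.019,2.68,-0.06
1,high,0.012,1.35,-0.81
2,high,0.016,1.75,-1.73
3,high,0.031,3.69,-3.69
4,high,0.038,4.35,-4.35
5,high,0.043,4.81,-4.81
6,high,0.017,1.87,-1.84
1,all,0.019,2.82,-0.13
2,all,0.022,3.01,0.99
3,all,0.021,4.14,-1.24
4,all,0.032,4.98,-4.87
5,all,0.041,5.61,-5.60
6,all,0.022,3.07,-1.63
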