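feature,icc,ci_low,ci_high,mdc,sem,mean_stroke,sd_stroke,n_stroke,mean_healthy,sd_healthy,n_healthy,t_stat,effect_size
L0,0.75,0.61,0.85,2.214,0.799,-0.3,0.4,68,1.0,1.6,42,5.3,1.24
L1,0.847,0.75,0.91,1.326,0.478,0.1,0.6,68,-1.7,0.6,42,-14.2,3.00
L2,0.851,0.76,0.91,1.126,0.406,0.0,0.6,68,-0.1,0.8,42,-0.9,0.15
L3,0.481,0.25,0.66,1.821,0.657,-0.0,0.4,68,0.2,0.4,42,2.0,0.50
L4,0.452,0.21,0.64,2.108,0.761,-0.0,0.4,68,0.4,0.5,42,3.6,0.91
L5,0.899,0.83,0.94,0.831,0.3,-0.4,0.4,68,-1.6,0.9,42,-7.9,1.87
L6,0.618,0.42,0.76,1.773,0.64,0.2,0.5,68,-0.5,0.6,42,-5.8,1.30
L7,0.796,0.67,0.88,1.426,0.514,-0.2,0.7,68,-0.5,0.9,42,-1.8,0.38
L8,0.684,0.51,0.8,1.197,0.432,-0.4,0.6,68,0.0,0.3,42,5.5,0.79
L9,0.431,0.19,0.62,2.138,0.771,-0.1,0.3,68,-0.3,0.5,42,-1.6,0.51
L10,0.369,0.11,0.58,2.05,0.74,0.1,0.4,68,0.2,0.4,42,1.5,0.25
L11,0.704,0.52,0.82,1.208,0.436,-0.1,0.4,68,0.5,0.5,42,6.2,1.36
gait_speed,0.963,0.92,0.98,0.137,0.049,0.4,0.3,68,1.1,0.2,42,15.2,2.6
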