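key,value
theta_hat1,0.86
assumed_true_theta,0.28
assumed_true_sigma2,21.62
window_a,50
window_b,500
alpha,0.05
beta,0.2
delta_design,-0.36
n1_sim,61
sigma2_first,19.94
sigma2_second,24.96
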