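measure,metric,r,p,reported_p,asterisk
VABS_communication,initial_rate,0.77,0.028,0.028,FALSE
VABS_communication,tau_s,-0.73,0.042,0.042,FALSE
VABS_communication,frac_fused_200AP_pct,0.89,0.004,0.004,TRUE
VABS_motor,initial_rate,0.90,0.002,0.002,TRUE
VABS_motor,tau_s,-0.88,0.005,0.005,TRUE
VABS_motor,frac_fused_200AP_pct,0.98,0.0009,<0.001,TRUE
CVI_total,initial_rate,-0.51,0.24,0.24,FALSE
CVI_total,tau_s,0.60,0.16,0.16,FALSE
CVI_total,frac_fused_200AP_pct,-0.63,0.13,0.13,FALSE
movement_disorder_count,initial_rate,-0.44,0.25,0.25,FALSE
movement_disorder_count,tau_s,0.57,0.14,0.14,FALSE
movement_disorder_count,frac_fused_200AP_pct,-0.44,0.25,0.25,FALSE
DBC_self_injury,initial_rate,0.25,0.59,0.59,FALSE
DBC_self_injury,tau_s,0.04,0.94,0.94,FALSE
DBC_self_injury,frac_fused_200AP_pct,0.07,0.88,0.88,FALSE
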