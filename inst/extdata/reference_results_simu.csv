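task,n,male_elite,male_novice,female_elite,female_novice,n_pcs,accuracy,hit,miss,fa,cr,d_prime,c
bird_dog_left,380,242,83,12,43,6,81.22,0.92,0.08,0.45,0.55,1.56,-0.66
bird_dog_right,387,244,88,11,44,7,81.98,0.90,0.10,0.49,0.51,1.34,-0.64
drop_jump,275,168,64,7,36,14,84.67,0.89,0.11,0.27,0.73,1.81,-0.29
hop_down_left,396,242,99,10,45,10,81.75,0.88,0.13,0.36,0.64,1.51,-0.40
hop_down_right,396,242,97,11,46,13,79.70,0.89,0.11,0.40,0.60,1.49,-0.50
l_hop_left,266,159,67,6,34,12,83.15,0.87,0.13,0.29,0.71,1.70,-0.29
l_hop_right,267,160,67,6,34,15,82.71,0.90,0.10,0.33,0.67,1.71,-0.41
lunge_left,399,246,97,12,44,18,80.70,0.93,0.07,0.50,0.50,1.47,-0.74
lunge_right,401,248,97,12,44,18,81.25,0.91,0.09,0.38,0.62,1.62,-0.51
step_down_left,399,246,98,12,43,12,75.19,0.87,0.13,0.52,0.48,1.07,-0.60
step_down_right,399,247,96,11,45,6,76.37,0.88,0.12,0.50,0.50,1.17,-0.60
t_balance_left,392,244,92,11,45,14,76.47,0.90,0.10,0.55,0.45,1.15,-0.71
t_balance_right,395,244,94,12,45,10,75.13,0.87,0.13,0.50,0.50,1.14,-0.58
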