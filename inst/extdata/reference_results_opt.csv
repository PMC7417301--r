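task,n,male_elite,male_novice,female_elite,female_novice,n_pcs,accuracy,hit,miss,fa,cr,d_prime,c
bird_dog_left,380,242,83,12,43,10,82.63,0.91,0.09,0.34,0.66,1.75,-0.46
bird_dog_right,387,244,88,11,44,18,80.88,0.90,0.10,0.36,0.64,1.62,-0.46
drop_jump,275,168,64,7,36,12,80.36,0.88,0.12,0.33,0.67,1.61,-0.37
hop_down_left,396,242,99,10,45,14,77.27,0.87,0.13,0.40,0.60,1.39,-0.45
hop_down_right,396,242,97,11,46,9,74.24,0.84,0.16,0.43,0.57,1.17,-0.40
l_hop_left,266,159,67,6,34,15,83.83,0.89,0.11,0.25,0.75,1.91,-0.27
l_hop_right,267,160,67,6,34,14,79.03,0.87,0.13,0.34,0.66,1.54,-0.35
lunge_left,399,246,97,12,44,11,78.20,0.87,0.13,0.38,0.62,1.43,-0.40
lunge_right,401,248,97,12,44,17,78.30,0.88,0.12,0.39,0.61,1.44,-0.44
step_down_left,399,246,98,12,43,17,75.94,0.84,0.16,0.40,0.60,1.28,-0.38
step_down_right,399,247,96,11,45,16,74.19,0.83,0.17,0.42,0.58,1.16,-0.37
t_balance_left,392,244,92,11,45,13,77.30,0.89,0.11,0.45,0.55,1.37,-0.56
t_balance_right,395,244,94,12,45,18,73.16,0.83,0.17,0.45,0.55,1.08,-0.41
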