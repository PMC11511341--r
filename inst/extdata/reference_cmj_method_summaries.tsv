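# Published per-method summary statistics (mean, SD) for countermovement-jump
# variables measured simultaneously by a marker-based motion-capture system and
# a markerless (pose-estimation) system, by recording side. n = 60 trials per
# cell (12 participants x 5 jumps). Units: phases s, jump height m.
variable	side	mean_marker	sd_marker	mean_markerless	sd_markerless	n
unweighting_phase_s	left	0.241	0.043	0.241	0.047	60
unweighting_phase_s	right	0.239	0.044	0.238	0.043	60
braking_phase_s	left	0.178	0.032	0.173	0.029	60
braking_phase_s	right	0.185	0.039	0.180	0.032	60
propulsive_phase_s	left	0.243	0.038	0.210	0.036	60
propulsive_phase_s	right	0.239	0.039	0.206	0.031	60
flight_time_s	left	0.547	0.065	0.608	0.086	60
flight_time_s	right	0.553	0.059	0.616	0.070	60
jump_height_m	left	0.340	0.076	0.362	0.074	60
jump_height_m	right	0.342	0.068	0.359	0.073	60
takeoff_com_vz_mps	left	2.33	0.30	2.25	0.27	60
takeoff_com_vz_mps	right	2.33	0.26	2.27	0.26	60
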