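group,window_start_month,window_end_month,category,total_cost_sek,n_treated
control,0,12,orthopaedics,106000,38
control,0,12,physiotherapy,178596,13
control,0,12,orthotics,1650,6
control,0,12,radiography_tests,37346,19
control,0,12,surgery,187439,7
control,0,12,drugs_injections,6933,18
control,0,12,paramedical,20790,5
index,0,12,specialised_MT,104580,40
index,0,12,orthopaedics,30000,15
index,0,12,physiotherapy,22878,2
index,0,12,orthotics,630,1
index,0,12,radiography_tests,19197,6
index,0,12,surgery,16340,1
index,0,12,drugs_injections,3141,3
index,0,12,paramedical,20054,5
control,12,96,specialised_MT,8190,2
control,12,96,orthopaedics,17936,4
control,12,96,physiotherapy,853392,11
control,12,96,orthotics,13248,1
control,12,96,surgery,72188,2
control,12,96,paramedical,312074,7
index,12,96,specialised_MT,2520,2
index,12,96,physiotherapy,23184,3
index,12,96,orthotics,1104,1
index,12,96,surgery,114890,5
index,12,96,paramedical,1600,1
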