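quantity,value
protocol_utility_index,0.737
protocol_utility_control,0.695
pooled_utility_recovered,0.811
pooled_utility_non_recovered,0.672
mean_cost_index_sek,9003
mean_cost_control_sek,49273
mean_cost_control_after_2sd_sek,33994
incremental_cost_sek,40270
incremental_cost_discounted_sek,36808
qaly_gain,0.159
qaly_gain_discounted,0.143
recovery_3mo_index_pct,69
recovery_3mo_control_pct,58
arm_n_index_0_12,40
arm_n_control_0_12,38
arm_n_index_13_96,38
arm_n_control_13_96,37
discount_rate,0.03
sek_per_eur,10
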