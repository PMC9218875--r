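# Final-stage behavioral task: 70/10 reward probabilities, reversal after
# 10 rewarded trials plus a geometric extension (p = 0.4).
p_high: 0.7
p_low: 0.1
rewards_to_reversal: 10
geometric_p: 0.4
variant: reward_counted
hazard: 0.05
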