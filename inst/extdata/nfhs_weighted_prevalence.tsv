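outcome	sex	prev_2016	prev_2021
hypertension	women	9.2	9.8
hypertension	men	13.5	15.3
diabetes	women	12.1	17.3
diabetes	men	15.7	22.5
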