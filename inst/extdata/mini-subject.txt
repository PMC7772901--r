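# wearnet subject fixture v1
# subject: MINI
# channel: chest ECG 4 8
# channel: wrist EDA 4 8
# channel: label labels 4 8
0.10	2.00	1
0.20	2.10	1
0.15	2.05	1
0.30	2.20	1
0.90	4.10	2
0.80	4.00	2
0.70	4.30	2
0.60	4.20	2
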