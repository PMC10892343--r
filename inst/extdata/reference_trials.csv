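subject,trial,estimated_cm,measured_cm
1,1,17.02,14.00
1,2,27.09,25.50
2,1,19.45,23.40
2,2,14.20,22.80
3,1,14.06,18.10
3,2,19.00,17.40
4,1,11.45,14.50
4,2,13.79,19.30
5,1,11.65,16.30
5,2,17.75,21.60
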