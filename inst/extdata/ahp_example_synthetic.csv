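parameter,ph,alkalinity,hardness,ca,mg,fe,fluoride,nitrate,sulfate
ph,1.000000000000000,1.000000000000000,1.000000000000000,0.500000000000000,0.500000000000000,0.500000000000000,0.333333333333333,0.250000000000000,0.333333333333333
alkalinity,1.000000000000000,1.000000000000000,0.500000000000000,0.500000000000000,0.500000000000000,0.333333333333333,0.333333333333333,0.250000000000000,0.333333333333333
hardness,1.000000000000000,2.000000000000000,1.000000000000000,1.000000000000000,1.000000000000000,0.500000000000000,0.500000000000000,0.333333333333333,0.500000000000000
ca,2.000000000000000,2.000000000000000,1.000000000000000,1.000000000000000,1.000000000000000,0.500000000000000,0.500000000000000,0.333333333333333,0.500000000000000
mg,2.000000000000000,2.000000000000000,1.000000000000000,1.000000000000000,1.000000000000000,0.500000000000000,0.500000000000000,0.333333333333333,0.500000000000000
fe,2.000000000000000,3.000000000000000,2.000000000000000,2.000000000000000,2.000000000000000,1.000000000000000,1.000000000000000,0.500000000000000,1.000000000000000
fluoride,3.000000000000000,3.000000000000000,2.000000000000000,2.000000000000000,2.000000000000000,1.000000000000000,1.000000000000000,1.000000000000000,1.000000000000000
nitrate,4.000000000000000,4.000000000000000,3.000000000000000,3.000000000000000,3.000000000000000,2.000000000000000,1.000000000000000,1.000000000000000,1.000000000000000
sulfate,3.000000000000000,3.000000000000000,2.000000000000000,2.000000000000000,2.000000000000000,1.000000000000000,1.000000000000000,1.000000000000000,1.000000000000000
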