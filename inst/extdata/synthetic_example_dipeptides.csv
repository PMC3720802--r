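id,sequence,activity
S1,IK,-2.5567
S2,HL,1.1454
S3,SM,1.4746
S4,104-101,-0.3164
S5,RH,0.8694
S6,102-102,-1.7672
S7,RW,-2.9965
S8,MW,-0.2319
S9,QS,-0.3326
S10,IC,-2.9736
S11,YI,2.2716
S12,105-102,2.1836
S13,102-A,-1.7719
S14,Y-105,0.2231
S15,DP,0.8671
S16,KH,3.9877
S17,VW,-2.2867
S18,AD,-0.8875
S19,102-Q,-1.2982
S20,TQ,1.8433
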