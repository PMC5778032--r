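variable,group,n,mean,sd
age,AD,34,69.86,9.00
age,aMCI,67,66.08,9.35
age,SCD,42,66.01,8.0
age,NC,54,67.22,6.15
education,AD,34,10.29,4.79
education,aMCI,67,10.73,4.15
education,SCD,42,11.88,4.17
education,NC,54,11.37,5.22
mmse,AD,34,17.88,5.24
mmse,aMCI,67,24.97,3.18
mmse,SCD,42,27.62,1.85
mmse,NC,54,28.31,2.26
avlt_immediate,AD,34,3.80,1.44
avlt_immediate,aMCI,67,5.89,1.62
avlt_immediate,SCD,42,7.95,1.86
avlt_immediate,NC,54,9.17,1.75
avlt_delayed,AD,34,1.12,1.67
avlt_delayed,aMCI,67,3.82,2.74
avlt_delayed,SCD,42,8.29,2.69
avlt_delayed,NC,54,10.06,2.59
moca,AD,34,13.58,4.84
moca,aMCI,67,20.17,3.71
moca,SCD,42,25.91,1.91
moca,NC,54,26.32,2.84
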