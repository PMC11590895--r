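class,accuracy,tpr,tnr,ppv,f1
non_coughing,88.88,92.57,78.41,92.41,92.49
coughing,88.88,78.41,92.57,78.82,78.61
Overall,88.88,85.49,85.49,85.61,85.55
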