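site,arm,n_participants,n_records,n_nonnegative,n_exhausted
china,standard,194,964,783,0
china,experimental,174,870,754,4
singapore,standard,195,972,754,21
singapore,experimental,184,919,743,21
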