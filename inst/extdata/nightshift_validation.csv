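stratum,self_report,record,count
cases,ever,ever,50
cases,ever,never,29
cases,never,ever,8
cases,never,never,138
controls,ever,ever,374
controls,ever,never,218
controls,never,ever,90
controls,never,never,1118
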