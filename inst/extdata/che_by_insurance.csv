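insurance,che,count
insured,yes,46
insured,no,201
non_insured,yes,148
non_insured,no,430
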