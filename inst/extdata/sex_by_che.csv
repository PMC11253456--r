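head_sex,che,count
male,yes,187
male,no,387
female,yes,60
female,no,191
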