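support	named_spurious	named_total	hypothetical_spurious	hypothetical_total
strong	8	8581	51	2824
fair	0	2498	46	8968
weak	0	2228	0	0
insufficient	0	0	44	24437
total	8	13307	141	36127
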