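chr17	7675110	7675111	rs0001
chr17	7675930	7675932	editsite
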