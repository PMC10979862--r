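chr13	21715711	21837530	H2bc13-H4bc2	histone
chr13	22035122	22043658	H2ac12-H2bc11	histone
chr13	23531044	23622558	H4c8-H1f4	histone
chr13	23683473	23764412	H2ac6-H1f1	histone
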