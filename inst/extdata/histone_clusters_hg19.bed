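chr1	149783434	149859466	Minor	histone
chr6	26017260	26285727	Major	histone
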