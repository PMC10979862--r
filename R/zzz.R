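# required so `:=` dispatches to data.table methods inside this package
.datatable.aware <- TRUE
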