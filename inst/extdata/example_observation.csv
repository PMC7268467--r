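"gene","variant","drug","outcome","relation","sideEffect"
"CYP3A5",52,"pegloticase","UNCHANGED","true","true"
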