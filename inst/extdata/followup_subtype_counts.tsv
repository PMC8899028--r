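label	count
19del	17
L858R	14
G719X	12
S768I	13
other_uncommon	15
multiple	14
wildtype	13
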