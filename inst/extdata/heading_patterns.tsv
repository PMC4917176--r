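pattern	label
^(background|introduction)$	introduction
^(materials?( and | & )methods?|methods?( and materials?)?|methods|experimental procedures?|study design|patients and methods)$	methods
^(results?( and |/| & )discussion|results?|discussion|findings)$	results_discussion
^(conclusions?|concluding remarks|summary and conclusions?)$	conclusion
^(availability|implementation)$	methods
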