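corpus	journals	documents	mentions	doc_mentions
full	3849	713634	3926176	1279111
medicine	650	152464	663988	170145
biology	430	126376	1628790	400691
bioinformatics	67	25851	797501	172099
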