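cue	attribute	value	direction
no	status	negated	pre
without	status	negated	pre
negative for	status	negated	pre
rather than	status	negated	pre
no evidence of	status	negated	pre
free of	status	negated	pre
absence of	status	negated	pre
probable	status	probable	pre
possible	status	probable	pre
probably	status	probable	pre
possibly	status	probable	pre
likely	status	probable	pre
may represent	status	probable	pre
suggest	status	probable	pre
suggests	status	probable	pre
suggestive of	status	probable	pre
suspicious for	status	probable	pre
cannot exclude	status	probable	pre
questionable	status	probable	pre
history of	temporality	historical	pre
known	temporality	historical	pre
previously seen	temporality	historical	pre
previously demonstrated	temporality	historical	pre
if	temporality	hypothetical	pre
should there be	temporality	hypothetical	pre
family history	experiencer	other	pre
mother	experiencer	other	pre
father	experiencer	other	pre
sibling	experiencer	other	pre
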