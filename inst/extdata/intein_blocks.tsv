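# Intein splicing-block patterns (conservative defaults; identical to
# cryptorf::default_intein_patterns()).  Override with your own file
# via the pattern_file config option / --patterns flag.
# alphabet: aa = scanned over the in-frame translation of the insertion
name	alphabet	pattern
block_A	aa	^[CST]
block_B	aa	T..H
block_F	aa	[LIVM]H[NQ]
block_G	aa	[HN][NS]$
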