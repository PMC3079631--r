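loop	offset	anchor	note
A	45	H53	inferred: H53 at local position 8
B	77	T85	inferred: T85 at local position 8 (also places R95/E96/R99)
C	146	H154	inferred: H154 at local position 8
D	177	Y182	inferred: Y182 at local position 5
E	212	A217	inferred: A217 at local position 5
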