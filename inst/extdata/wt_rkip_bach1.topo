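Source	Target	Type
BACH1	BACH1	2
BACH1	SLUG	1
BACH1	RKIP	2
RKIP	SNAIL	2
SNAIL	RKIP	2
RKIP	let7	1
let7	BACH1	2
LIN28	let7	2
let7	LIN28	2
miR145	OCT4	2
OCT4	miR145	2
ERa66	ERa36	2
ERa36	ZEB1	1
miR200	LIN28	2
miR145	ERa66	2
miR145	ZEB1	2
ZEB1	miR145	2
SLUG	ERa66	2
ERa66	SLUG	2
ZEB1	miR200	2
miR200	ZEB1	2
SNAIL	ZEB1	1
SNAIL	miR200	2
ZEB1	CDH1	2
SLUG	CDH1	2
ZEB1	ERa66	2
SNAIL	CDH1	2
SLUG	ZEB1	1
OCT4	LIN28	1
LIN28	OCT4	1
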