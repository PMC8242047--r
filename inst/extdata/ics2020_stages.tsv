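stage	base_age	top_age
Berriasian	145	139.8
Valanginian	139.8	132.9
Hauterivian	132.9	129.4
Barremian	129.4	125
Aptian	125	113
Albian	113	100.5
Cenomanian	100.5	93.9
Turonian	93.9	89.8
Coniacian	89.8	86.3
Santonian	86.3	83.6
Campanian	83.6	72.1
Maastrichtian	72.1	66
Danian	66	61.6
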