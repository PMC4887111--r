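name	start	end
B-C	113	133
C-D	148	163
F	202	217
F-G	218	237
G'-H	238	255
G-H	256	270
H	271	282
J-K	330	355
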