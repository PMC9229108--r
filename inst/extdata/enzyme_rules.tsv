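name	ec	p1	p1_prime_block
pepsin_pH1.3	3.4.23.1	F,L
trypsin	3.4.21.4	K,R	P
chymotrypsin_A	3.4.21.1	W,Y,F	P
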