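dataset	W	N1	N2	N3	R	total
sleep-EDF	7927	2804	17799	5703	7717	41950
ISRUC-III	1817	1248	2678	2035	1111	8889
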