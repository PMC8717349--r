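sex	age	year	n_murina_ussuriensis	n_myotis_ikonnikovi
f	ad	2015	11	10
f	ad	2016	2	2
f	ad	2017	12	6
f	j	2015	2	1
f	j	2016	0	2
f	j	2017	1	0
m	ad	2015	13	6
m	ad	2016	8	1
m	ad	2017	4	1
m	j	2015	0	11
m	j	2016	0	1
m	j	2017	0	1
NA	NA	2016	0	3
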