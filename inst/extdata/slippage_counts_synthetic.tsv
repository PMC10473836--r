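strain	condition	experiment	selective1	selective2	nonselective1	nonselective2	dilutionSelective	dilutionNonselective
RTS1-ura4sd20	barrier_on	1	52	48	205	195	10	10000
RTS1-ura4sd20	barrier_on	2	61	55	210	188	10	10000
RTS1-ura4sd20	barrier_on	3	44	50	199	201	10	10000
RTS1-ura4sd20	barrier_off	1	11	9	204	196	10	10000
RTS1-ura4sd20	barrier_off	2	8	12	190	212	10	10000
RTS1-ura4sd20	barrier_off	3	10	10	207	193	10	10000
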