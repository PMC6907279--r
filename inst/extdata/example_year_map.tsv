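pmid	year
PM01	1962
PM02	1970
PM03	1988
PM04	1991
PM05	1975
PM06	1979
PM07	1983
PM08	1985
PM09	1977
PM10	1981
PM11	1968
PM12	1972
PM13	1980
PM14	1986
PM15	1978
PM16	1982
PM17	1990
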