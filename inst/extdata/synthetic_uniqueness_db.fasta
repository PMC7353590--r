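>P01602_synthetic synthetic carrier sequence
TFALEVTRHEFQYVRDKEFPFYCIDALMRIDIQMTQSPSTLSASVGDREEVPFECVDTVGGCYDCGLIFATHEPLKNY
>A0A0B4J1V2_synthetic synthetic carrier sequence
KMDSFQFCVTVFQIIEEHLVPWSTNSRLTISKKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGYRC
>Q07020_synthetic synthetic carrier sequence
LNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATACNQVVLKISDFPNAWFRGSLHKKDVRR
>IGHG1_CH_synthetic synthetic carrier sequence
YSAGMKYPFMRCGAQSTMVCLEYRHTFYVKMGLKWKMWELTNGRKLVHQNWLFCDCQSEGYYMAQAEPGNHNFVHPCDARYMKLHWVNLKWRQDYLCTVWQTLFPVWWLS
>IGKC_synthetic synthetic carrier sequence
CEHAQYWNWGNLHWCGKMGFQLRAKLTNAMEDGFLYCEYKQQDVLAIYFGQEKISNLQMCSQRTGWLPGAMPLPRTRIEG
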