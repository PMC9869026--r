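block	start	end	anchor_offset	anchor_seq
C1	10	29	12	GGCAAAGGGTCGTGG
C2	340	359	342	AGCACGTCCCACTGC
C3	520	539	522	CCTATTTGCCGCACG
C4	790	809	792	GTACCATCGAGCACC
C5	910	929	912	GTGTACCACGCAGTG
C6	1065	1084	1067	GGCACAGTTACCGCG
C7	1230	1249	1232	TATTCTACGATGCGC
C8	1480	1499	1482	CTTGCAACTTTGCGA
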