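# Synthetic disease-to-phenotype annotation fixture for the mini ontology.
# Disease IDs are fabricated (OMIM:9xxxxx) except OMIM:109400, which stands in
# for the NBCCS annotation profile; term sets are invented for testing only.
disease_id	hpo_id
OMIM:109400	HP:0010603
OMIM:109400	HP:0010610
OMIM:109400	HP:0002671
OMIM:109400	HP:0005462
OMIM:109400	HP:0002885
OMIM:109400	HP:0000256
OMIM:109400	HP:0000892
OMIM:109400	HP:0000925
OMIM:900001	HP:0002885
OMIM:900001	HP:0000256
OMIM:900001	HP:0002119
OMIM:900002	HP:0002671
OMIM:900002	HP:0000518
OMIM:900002	HP:0001574
OMIM:900003	HP:0000892
OMIM:900003	HP:0008422
OMIM:900003	HP:0010442
OMIM:900003	HP:0000175
OMIM:900004	HP:0000256
OMIM:900004	HP:0000098
OMIM:900004	HP:0002119
OMIM:900004	HP:0000107
OMIM:900005	HP:0000518
OMIM:900005	HP:0000589
OMIM:900005	HP:0000568
OMIM:900006	HP:0000175
OMIM:900006	HP:0410030
OMIM:900006	HP:0000695
OMIM:900007	HP:0000104
OMIM:900007	HP:0000107
OMIM:900007	HP:0000119
OMIM:900008	HP:0002126
OMIM:900008	HP:0002308
OMIM:900008	HP:0100702
OMIM:900008	HP:0000365
OMIM:900009	HP:0002514
OMIM:900009	HP:0005462
OMIM:900009	HP:0002119
OMIM:900010	HP:0000365
OMIM:900010	HP:0000598
OMIM:900011	HP:0000486
OMIM:900011	HP:0000519
OMIM:900011	HP:0000568
OMIM:900012	HP:0010603
OMIM:900012	HP:0000153
OMIM:900012	HP:0000695
OMIM:900013	HP:0002664
OMIM:900013	HP:0002885
OMIM:900013	HP:0002671
OMIM:900014	HP:0000924
OMIM:900014	HP:0000925
OMIM:900014	HP:0000772
OMIM:900014	HP:0000892
OMIM:900015	HP:0000098
OMIM:900015	HP:0001507
OMIM:900016	HP:0004482
OMIM:900016	HP:0000240
OMIM:900017	HP:0010610
OMIM:900017	HP:0001574
OMIM:900017	HP:0000486
OMIM:900018	HP:0000077
OMIM:900018	HP:0000104
OMIM:900019	HP:0012443
OMIM:900019	HP:0002308
OMIM:900019	HP:0000707
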