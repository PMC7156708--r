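surname	count
White	880513
Davis	846313
Johnson	843682
Okafor	841532
Smith	823751
Berry	814108
Garcia	748251
Patel	664247
Washington	648605
Lopez	636033
Hernandez	593008
Martinez	579362
Bell	506498
Nguyen	469591
Price	430122
Brown	418752
Chen	414679
Williams	261095
Doe	233609
Stone	129146
Kim	125527
Young	110151
Miller	79113
Parker	78627
Wright	77886
Adams	77681
Hamilton	77013
Choi	77010
Scott	76611
Wilson	75740
Ford	75403
Mensah	74998
Ruiz	74651
Hughes	74061
Tran	73546
Robinson	72539
Thomas	72470
Ali	72302
Green	71034
Ivanov	68057
Collins	67993
West	66964
Martin	66900
Clark	66653
Mcdonald	66336
Morris	66273
Silva	65734
Perez	64907
Mitchell	62801
Richardson	62093
Rossi	61189
Cruz	60792
Jordan	60152
Roberts	59934
Bryant	59549
Graham	59220
Lee	59039
Flores	58759
Sullivan	58692
Kaur	57993
Alvarez	57606
Cooper	57582
Morales	55493
Harris	54851
Gomez	54221
Diaz	54088
Bennett	53434
Ward	51693
Baker	51242
Osei	50565
Russell	50144
Ferrari	49934
Alexander	49578
Nelson	49553
Gibson	49017
Walker	48989
Cole	48762
Khan	48326
Wells	47224
Howard	46579
Petrov	46436
Kennedy	45929
Edwards	45371
Watson	45144
Fisher	43046
Reynolds	42919
Wallace	42917
Foster	41263
Turner	41211
Reed	41211
Taylor	41195
Ortiz	38414
Owens	36284
Jackson	35824
Allen	34929
King	34608
Gonzales	32922
Campbell	31951
Woo	31670
Anderson	31289
Myers	31189
Thompson	31122
Hall	30439
Bailey	30114
Cox	28799
Marshall	28615
Harrison	28531
Rivera	27818
Hill	26754
Simmons	26726
James	24501
Stewart	21790
Evans	20976
Murphy	19335
Brooks	18788
Singh	18774
Griffin	17467
Hayes	17419
Gutierrez	17405
Mendoza	16781
Lewis	16708
Morgan	15889
Reyes	15255
Phillips	13801
Ramos	12733
Rogers	11341
Santos	9204
Chavez	7308
Wood	6959
Moore	6705
Cook	3554
Carter	3230
Torres	3110
Peterson	750
Ramirez	706
Sanchez	435
Woods	302
Kelly	245
Ellis	230
Walks	150
Gray	139
Zyzzyva	78
Blorft	73
Qoph	13
Xantippe	5
Rarename	1
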