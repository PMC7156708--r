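name	birth_year	count
James	1921	1697
James	1922	1911
James	1976	8899
James	2015	3314
Maria	1885	7618
Maria	1922	8950
Maria	1990	4899
Robert	1885	611
Robert	1917	2835
Robert	1973	8742
Elena	1891	7365
Elena	1920	8860
Elena	2007	1126
Michael	1971	166
Michael	1986	640
Aisha	1907	6778
Aisha	1911	3113
Aisha	1974	2825
David	1893	6631
David	1957	3550
David	1976	1155
David	2001	3569
Susan	1906	5525
Susan	1909	1297
Susan	1960	2019
Susan	1979	1410
Carlos	1880	8085
Carlos	1928	4005
Carlos	1940	6
Carlos	1995	8867
Linda	1882	4544
Linda	1891	7731
Linda	1892	3274
Linda	1930	5134
Ahmed	1882	2136
Ahmed	1907	3962
Ahmed	1961	5084
Ahmed	1972	8421
Grace	1933	6104
Grace	1981	3075
Thomas	1922	7109
Thomas	1964	6034
Thomas	1981	53
Priya	1897	3189
Priya	1915	7199
Priya	1934	2658
Priya	1950	2697
Daniel	1917	3949
Daniel	1985	1943
Daniel	1993	5416
Rosa	1909	6847
Rosa	1938	7114
Rosa	1992	3635
Kevin	1967	1979
Kevin	1993	6539
Anna	1889	7293
Anna	1891	1629
Anna	1930	3363
Jane	1903	7082
Jane	1932	985
Jane	1979	5528
Jane	1999	8911
John	1912	609
John	1971	1832
John	2002	3940
Mary	1884	932
Mary	1987	982
Mary	2014	2987
Patricia	1909	1082
Patricia	2001	6535
Jennifer	1888	3787
Jennifer	1990	4064
Elizabeth	1952	6279
Elizabeth	1958	5185
Elizabeth	1987	5144
Barbara	1896	7346
Barbara	1961	6421
Barbara	1977	98
Jessica	1927	8669
Jessica	1947	5490
Jessica	1953	3192
Sarah	1949	3618
Sarah	1968	2155
Sarah	1987	8951
Karen	1881	201
Karen	1954	1220
Lisa	1901	3845
Lisa	1926	5501
Lisa	1928	8328
Nancy	1932	2754
Nancy	1938	6235
Nancy	1948	232
Nancy	2004	2045
Betty	1906	1202
Betty	2016	4103
Margaret	1932	2548
Margaret	1963	2270
Margaret	1966	6480
Margaret	1980	114
Sandra	1906	8788
Sandra	1933	1138
Sandra	1936	1757
Sandra	1986	7072
Ashley	1902	4367
Ashley	1940	5489
Ashley	1962	3662
Ashley	1981	2545
Kimberly	1960	1240
Kimberly	1970	1539
Kimberly	1979	1620
Kimberly	1990	6676
Emily	1882	929
Emily	1889	5810
Emily	1935	4258
Emily	1964	7089
Donna	1921	6831
Donna	1931	8130
Donna	1932	830
Donna	1977	6573
Michelle	1912	3983
Michelle	1964	5809
Dorothy	1924	8743
Dorothy	2005	1585
Dorothy	2009	3220
Carol	1981	8291
Carol	2001	6057
Carol	2015	3035
Carol	2016	2285
Amanda	1894	3144
Amanda	1954	4928
Amanda	2002	4715
Melissa	1887	8071
Melissa	1963	4205
Melissa	1978	4276
Melissa	1999	7759
Deborah	1897	5436
Deborah	1982	5846
Stephanie	1887	3283
Stephanie	1889	1857
Stephanie	1898	8359
Stephanie	1993	5748
Rebecca	1933	593
Rebecca	2008	2450
Sharon	1938	277
Sharon	1969	8235
Laura	1887	8864
Laura	1899	1394
Cynthia	1925	4860
Cynthia	1964	2121
Kathleen	1882	2070
Kathleen	1891	246
Kathleen	2001	7564
Amy	1900	751
Amy	1909	3670
Amy	1930	942
Amy	1962	7329
Angela	1901	3736
Angela	1998	4791
Angela	2011	4395
Shirley	1898	4121
Shirley	1942	1391
Brenda	1947	3168
Brenda	1977	4520
Brenda	1995	6845
Brenda	2014	4006
Emma	1892	4909
Emma	1914	352
Emma	1936	8590
Emma	1977	2916
Olivia	1906	3666
Olivia	1944	1923
Olivia	1976	8254
Sophia	1907	6306
Sophia	1911	2423
Isabella	1913	8191
Isabella	1977	5084
Mia	1907	534
Mia	1927	5274
Charlotte	1928	8226
Charlotte	1974	7756
Charlotte	1983	7095
Amelia	1883	6048
Amelia	1937	1069
Amelia	1944	5477
Amelia	1978	2762
William	1890	4045
William	1971	7831
William	2016	8101
Richard	1913	1769
Richard	1919	6971
Richard	1934	5014
Richard	1992	3904
Joseph	1889	8985
Joseph	1948	8259
Joseph	1950	1270
Joseph	1967	8685
Charles	1882	491
Charles	1908	6446
Charles	1924	4117
Charles	1970	4582
Christopher	1955	4060
Christopher	1967	4258
Matthew	1985	7709
Matthew	1991	2588
Matthew	2014	5891
Anthony	1887	2916
Anthony	1915	8888
Anthony	1959	5634
Mark	1914	1509
Mark	1935	4800
Mark	1946	1833
Donald	1908	7472
Donald	1923	7879
Donald	2011	4231
Steven	1958	7475
Steven	1984	1631
Steven	2014	2199
Paul	1912	2134
Paul	1947	5698
Paul	1984	4199
Andrew	1893	3935
Andrew	1935	1540
Andrew	1940	8091
Joshua	1887	2345
Joshua	1949	6462
Joshua	1969	5463
Kenneth	1950	6307
Kenneth	1970	2232
Kenneth	1985	3623
Kenneth	1997	8385
George	1944	1557
George	2001	5167
Timothy	1912	3586
Timothy	1961	73
Ronald	1892	6766
Ronald	1912	7419
Ronald	1957	4736
Ronald	1999	6741
Edward	1919	8068
Edward	1966	3962
Edward	1970	2366
Jason	1882	4178
Jason	1901	5396
Jeffrey	1888	5794
Jeffrey	1906	3170
Jeffrey	1978	205
Ryan	1899	8682
Ryan	1979	3686
Jacob	1887	7064
Jacob	1896	7930
Jacob	1932	5057
Jacob	1967	3227
Gary	1898	5368
Gary	1999	6582
Nicholas	1889	3184
Nicholas	1956	313
Eric	1918	4665
Eric	1986	8488
Eric	1997	6209
Jonathan	1885	5022
Jonathan	2008	6717
Stephen	1882	1334
Stephen	1924	88
Stephen	2000	3090
Stephen	2005	8806
Larry	1886	8816
Larry	1917	8142
Justin	1904	1442
Justin	1928	5023
Justin	1953	8855
Scott	1940	1403
Scott	1951	1044
Scott	1970	1100
Brandon	1939	4285
Brandon	1972	590
Brandon	1974	984
Brandon	2005	900
Benjamin	1895	7323
Benjamin	1964	4350
Benjamin	1980	3059
Samuel	1971	77
Samuel	2004	4901
Samuel	2007	6037
Gregory	1943	2143
Gregory	2013	7223
Alexander	1932	7383
Alexander	1966	1331
Frank	1885	1382
Frank	1912	933
Frank	1922	1762
Frank	1951	8888
Patrick	1906	8021
Patrick	1941	829
Raymond	1906	3534
Raymond	1956	6005
Jack	1890	2994
Jack	1953	1483
Dennis	1925	7959
Dennis	1948	4787
Dennis	1963	8445
Jerry	1921	4512
Jerry	1981	1462
Jerry	1982	3694
Jerry	1988	7579
Tyler	1970	6776
Tyler	1983	3753
Aaron	1976	1424
Aaron	2000	1137
Omar	1901	3090
Omar	1906	7472
Omar	1916	4620
Omar	1942	3538
Fatima	1935	5326
Fatima	1946	3002
Fatima	1973	3030
Wei	1920	3852
Wei	1951	8399
Wei	2004	1204
Wei	2016	1990
Ming	1968	8228
Ming	1989	8808
Ming	1994	4660
Ming	1997	8923
Yuki	1890	3822
Yuki	1962	23
Hana	1931	1855
Hana	1986	302
Hana	1993	7876
Hana	1997	2953
Ravi	1896	4210
Ravi	1934	4860
Anjali	1905	2981
Anjali	1948	1376
Anjali	1981	3697
Kofi	1891	5643
Kofi	1957	5642
Ama	1900	1957
Ama	1903	8498
Ama	1945	5762
Ama	1951	6154
Dmitri	1880	531
Dmitri	1900	1758
Dmitri	2006	2719
Dmitri	2008	7805
Olga	1938	1506
Olga	1954	237
Olga	1973	8188
Luca	1935	3577
Luca	1981	2045
Luca	1987	6315
Giulia	1890	8942
Giulia	1926	7350
Giulia	1990	5091
Mateo	1904	8711
Mateo	1962	7598
Mateo	1966	1305
Mateo	1998	7199
Lucia	1937	7604
Lucia	1948	8706
Lucia	1970	5289
Lucia	1986	2858
Noah	2011	7516
Noah	2012	6288
Liam	1907	7208
Liam	1942	5249
Liam	1991	4112
Ethan	1880	3152
Ethan	1926	4467
Ava	1880	4309
Ava	1910	3485
Ava	1928	2639
Ava	1946	299
Zz	1990	4
Oldtimey	1850	500
Futuro	2020	500
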