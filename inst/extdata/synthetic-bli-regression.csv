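"country","educ","hr","dwbf","lmi"
"SYN01",99.4985,4.77,41.9192,0.0733
"SYN02",58.0324,13.95,4.81088,0.0966
"SYN03",49.3867,14.54,3.14407,0.0772
"SYN04",0.757733,15.62,0.764471,0.1682
"SYN05",92.1052,5.28,17.3309,0.0303
"SYN06",65.2175,2.24,17.5795,0.1549
"SYN07",42.5221,25.26,0.00451811,0.0942
"SYN08",13.6685,13.35,2.49574,0.1661
"SYN09",86.6371,1.48,3.20575,0.0457
"SYN10",53.5968,17.62,0.660631,0.0391
"SYN11",49.5182,20.23,10.4177,0.0317
"SYN12",33.6931,19.64,3.58702e-06,0.0339
"SYN13",55.1471,13.74,0.00150549,0.0692
"SYN14",51.1783,23,2.44722,0.02
"SYN15",60.8501,9.19,3.81597,0.1566
"SYN16",39.9202,16.67,1.78729,0.1182
"SYN17",41.0436,19.24,1.87927,0.0959
"SYN18",60.9171,7.63,12.9914,0.1001
"SYN19",93.8835,5.17,47.1359,0.1515
"SYN20",76.6844,25.45,23.5688,0.0272
"SYN21",51.0338,14.11,8.37384,0.1487
"SYN22",25.6779,24.01,1.67125,0.0424
"SYN23",97.1082,6.58,47.5087,0.1601
"SYN24",89.0486,9.86,15.9972,0.0355
"SYN25",2.43742,15.56,0.398566,0.1647
"SYN26",71.8901,19.58,39.3506,0.1753
"SYN27",91.8376,18.83,7.76535,0.0149
"SYN28",86.4604,12.33,1.01318,0.0387
"SYN29",38.8035,4.74,0.023438,0.1062
"SYN30",78.3943,3.07,0.577792,0.01
"SYN31",84.4327,16.12,32.5116,0.091
"SYN32",11.8521,17.41,0.000630225,0.1082
"SYN33",16.7518,25.98,0.975733,0.0147
"SYN34",95.0407,18.01,0.328141,0.0051
"SYN35",99.7559,4.12,37.283,0.0317
"SYN36",82.5297,22.86,9.13378,0.0134
"SYN37",89.5324,25.33,0.0896886,0.1699
"SYN38",70.5359,9.84,0.059801,0.0364
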