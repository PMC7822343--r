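"country","dwbf"
"SYN01",41.9192
"SYN02",4.81088
"SYN03",3.14407
"SYN04",0.764471
"SYN05",17.3309
"SYN06",17.5795
"SYN07",0.00451811
"SYN08",2.49574
"SYN09",3.20575
"SYN10",0.660631
"SYN11",10.4177
"SYN12",3.58702e-06
"SYN13",0.00150549
"SYN14",2.44722
"SYN15",3.81597
"SYN16",1.78729
"SYN17",1.87927
"SYN18",12.9914
"SYN19",47.1359
"SYN20",23.5688
"SYN21",8.37384
"SYN22",1.67125
"SYN23",47.5087
"SYN24",15.9972
"SYN25",0.398566
"SYN26",39.3506
"SYN27",7.76535
"SYN28",1.01318
"SYN29",0.023438
"SYN30",0.577792
"SYN31",32.5116
"SYN32",0.000630225
"SYN33",0.975733
"SYN34",0.328141
"SYN35",37.283
"SYN36",9.13378
"SYN37",0.0896886
"SYN38",0.059801
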