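residue,Plr,Chrg,Hydpthy,stablty,ss_stability,vanderWaal,chargetransf,chargedonar,averhydrophocitiy,coilConformation,IsoElectric,RofGyr,EIIP,BalabanIndex,ShapeIndex,weighted_upper_domination,weighted_lower_domination,weighted_diameter,circumference,average_weighted_degree,weighted_periphery_size
ALA,8.1,0,1.8,1.42,0.83,1,0,0,0.62,0.824,6,0.77,0.0373,2.5395388613593903,2.2700556100296621,42.016999999999996,24.021999999999998,40.021000000000001,0,20.414399999999997,2
ARG,10.5,1,-4.5,0.98,0.93,6.13,0,0,-2.53,0.893,10.76,2.38,0.0959,3.0144468184377322,5.163902460147014,84.037999999999997,48.043999999999997,102.07199999999997,0,23.108000000000001,2
ASN,11.6,0,-3.5,0.67,0.89,2.95,1,0,-0.78,1.167,5.41,1.45,0.0036,3.0988280941131414,3.663902460147014,72.022999999999996,36.033000000000001,64.042999999999992,0,22.515249999999998,3
ASP,13,-1,-3.5,1.01,0.54,2.78,1,0,-0.9,1.197,2.77,1.43,0.1263,3.0988280941131414,3.663902460147014,74.015000000000001,36.033000000000001,64.042999999999992,0,22.764249999999997,3
CYS,5.5,0,2.5,0.7,1.19,2.43,0,1,0.29,0.953,5.07,1.22,0.0829,2.754184786037662,2.8080604124904469,62.066000000000003,36.033000000000001,68.093000000000004,0,24.357166666666664,1
GLN,10.5,0,-3.5,1.11,1.1,3.95,1,0,-0.85,0.947,5.65,1.75,0.0761,3.060820561162787,4.163902460147014,72.022999999999996,36.033000000000001,76.053999999999988,0,22.682666666666666,3
GLU,12.3,-1,-3.5,1.51,0.37,3.78,1,0,-0.74,0.761,3.22,1.77,0.0058,3.060820561162787,4.163902460147014,74.015000000000001,36.033000000000001,76.053999999999988,0,22.904,3
GLY,9,0,-0.4,0.57,0.75,0,0,0,0.48,1.251,5.97,0,0.005,1.9747448713915894,1.9142135623730949,30.006,24.021999999999998,40.021000000000001,0,19.512499999999999,1
HIS,10.4,0.1,-3.2,1,0.87,4.66,1,1,-0.4,1.068,7.59,1.78,0.0242,2.1084672021407385,4.8256985026954888,70.030999999999992,48.043999999999997,78.049999999999983,5,25.418799999999997,1
ILE,5.2,0,4.5,1.08,1.6,4,0,0,1.38,0.886,6.02,1.56,0,3.2924781560754957,3.7187440150134061,54.027999999999992,48.043999999999997,64.042999999999992,0,21.767249999999997,1
LEU,4.9,0,3.8,1.21,1.3,4,0,0,1.06,0.884,5.98,1.54,0,3.0988280941131414,3.663902460147014,66.038999999999987,36.033000000000001,64.042999999999992,0,21.767249999999997,2
LYS,11.3,1,-3.9,1.16,0.74,4.77,0,0,-1.5,0.897,9.74,2.08,0.0371,2.8766225950797444,4.3080604124904465,68.034999999999997,48.043999999999997,88.064999999999984,0,22.239555555555555,1
MET,5.7,0,1.9,1.45,1.05,4.43,0,1,0.64,0.81,5.74,1.8,0.0823,2.862065598305084,3.8080604124904469,74.076999999999998,48.043999999999997,96.10299999999998,0,26.779499999999999,1
PHE,5.2,0,2.8,1.13,1.38,5.89,1,1,1.19,0.797,5.48,1.9,0.0946,2.1324849608098977,5.3256985026954888,78.049999999999983,48.043999999999997,88.064999999999984,6,24.565999999999999,1
PRO,8,0,-1.6,0.57,0.55,2.72,0,0,0.12,1.54,6.3,1.25,0.0198,2.1399633186493645,3.4318516525781368,42.016999999999996,36.033000000000001,54.027999999999999,5,25.161999999999999,1
SER,9.2,0,-0.8,0.77,0.75,1.6,0,0,-0.18,1.13,5.68,1.08,0.0829,2.754184786037662,2.8080604124904469,46.005000000000003,36.033000000000001,52.032000000000004,0,21.68033333333333,2
THR,8.6,0,-0.7,0.83,1.19,2.6,0,0,-0.05,1.148,5.6,1.24,0.0941,3.1442082073698243,3.1807392125526213,58.016000000000005,36.033000000000001,52.032000000000004,0,22.014857142857142,3
TRP,5.4,0,-0.9,1.08,1.37,8.08,1,1,0.81,0.941,5.89,2.21,0.0548,1.8712979288852583,6.8088617502898812,92.056999999999988,60.054999999999993,100.07599999999998,9,26.450428571428571,1
TYR,6.2,0,-1.3,0.69,1.47,6.47,1,1,0.26,1.109,5.66,2.13,0.0516,2.1680936223289127,5.7195453528128404,82.037999999999982,48.043999999999997,100.07599999999998,6,24.852999999999998,2
VAL,5.9,0,4.2,1.06,1.7,3,0,0,1.08,0.772,5.96,1.29,0.0057,3.1442082073698243,3.1807392125526213,54.027999999999992,36.033000000000001,52.032000000000004,0,21.445142857142855,2
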