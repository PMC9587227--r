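belt,humidity,belt_name,humidity_name,name
1,1,polar,semisaturated,polar semisaturated
1,2,polar,superhumid,polar superhumid
1,3,polar,perhumid,polar perhumid
1,4,polar,humid,polar humid
1,5,polar,subhumid,polar subhumid
1,6,polar,semiarid,polar semiarid
1,7,polar,arid,polar arid
1,8,polar,perarid,polar perarid
1,9,polar,superarid,polar superarid
1,10,polar,semiparched,polar semiparched
2,1,subpolar,semisaturated,subpolar semisaturated
2,2,subpolar,superhumid,subpolar superhumid
2,3,subpolar,perhumid,subpolar perhumid
2,4,subpolar,humid,subpolar humid
2,5,subpolar,subhumid,subpolar subhumid
2,6,subpolar,semiarid,subpolar semiarid
2,7,subpolar,arid,subpolar arid
2,8,subpolar,perarid,subpolar perarid
2,9,subpolar,superarid,subpolar superarid
2,10,subpolar,semiparched,subpolar semiparched
3,1,boreal,semisaturated,boreal semisaturated
3,2,boreal,superhumid,boreal superhumid
3,3,boreal,perhumid,boreal perhumid
3,4,boreal,humid,boreal humid
3,5,boreal,subhumid,boreal subhumid
3,6,boreal,semiarid,boreal semiarid
3,7,boreal,arid,boreal arid
3,8,boreal,perarid,boreal perarid
3,9,boreal,superarid,boreal superarid
3,10,boreal,semiparched,boreal semiparched
4,1,cool temperate,semisaturated,cool temperate semisaturated
4,2,cool temperate,superhumid,cool temperate superhumid
4,3,cool temperate,perhumid,cool temperate perhumid
4,4,cool temperate,humid,cool temperate humid
4,5,cool temperate,subhumid,cool temperate subhumid
4,6,cool temperate,semiarid,cool temperate semiarid
4,7,cool temperate,arid,cool temperate arid
4,8,cool temperate,perarid,cool temperate perarid
4,9,cool temperate,superarid,cool temperate superarid
4,10,cool temperate,semiparched,cool temperate semiparched
5,1,warm temperate,semisaturated,warm temperate semisaturated
5,2,warm temperate,superhumid,warm temperate superhumid
5,3,warm temperate,perhumid,warm temperate perhumid
5,4,warm temperate,humid,warm temperate humid
5,5,warm temperate,subhumid,warm temperate subhumid
5,6,warm temperate,semiarid,warm temperate semiarid
5,7,warm temperate,arid,warm temperate arid
5,8,warm temperate,perarid,warm temperate perarid
5,9,warm temperate,superarid,warm temperate superarid
5,10,warm temperate,semiparched,warm temperate semiparched
6,1,tropical,semisaturated,tropical semisaturated
6,2,tropical,superhumid,tropical superhumid
6,3,tropical,perhumid,tropical perhumid
6,4,tropical,humid,tropical humid
6,5,tropical,subhumid,tropical subhumid
6,6,tropical,semiarid,tropical semiarid
6,7,tropical,arid,tropical arid
6,8,tropical,perarid,tropical perarid
6,9,tropical,superarid,tropical superarid
6,10,tropical,semiparched,tropical semiparched
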