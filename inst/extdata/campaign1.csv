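ExpNo,Batch,Objective,Conf,LiSalt,LiSaltEq,Acid,AcceptorEq,ConcM,PartEt2O,PartMeCN,MS,TempC,YieldPct,BetaPct
1,1,beta,alpha,LiPF6,3.4,Oxalic,1.7,0.18,0.51,0.05,3A,25,87,69
2,1,beta,beta,LiI,1.5,Acetic,1.3,0.3,0.29,0.06,4A,25,96,13
3,1,beta,beta,LiI,3.5,TFA,2.8,0.26,0.51,0.08,3A,0,69,11
4,1,beta,alpha,LiI,1.6,None,1.9,0.27,0.11,0.41,3A,25,13,36
5,1,beta,alpha,LiClO4,1.7,Acetic,1.4,0.25,0.11,0.81,3A,0,64,78
6,1,beta,beta,LiNTf2,2.2,Oxalic,1.7,0.19,0.41,0.08,3A,0,61,63
7,1,beta,beta,LiClO4,1.7,None,1.8,0.18,0.19,0.11,None,0,59,48
8,1,beta,beta,LiClO4,3,Acetic,2.2,0.25,0.56,0.16,4A,25,74,47
9,1,beta,alpha,LiBF4,2.6,Oxalic,3,0.22,0.75,0.18,4A,25,69,73
10,1,beta,alpha,LiB(C6F5)4,1,Acetic,2.1,0.24,0.65,0.28,5A,25,10,0
11,2,beta,alpha,LiPF6,2.8,Oxalic,1.5,0.17,0.33,0.04,None,25,97,18
12,2,beta,beta,LiOTf,1.5,Formic,3,0.09,0.44,0.15,None,25,81,49
13,2,beta,beta,LiNTf2,3.2,Formic,0.8,0.11,0.15,0.6,4A,0,28,86
14,2,beta,alpha,LiOTf,4.6,Oxalic,1.9,0.13,0.05,0.9,4A,25,97,64
15,2,beta,beta,LiPF6,4.1,Acetic,2.2,0.12,0.8,0.12,3A,25,98,65
16,3,beta,alpha,LiNTf2,4.8,TFA,1.2,0.12,0.69,0.28,4A,0,84,78
17,3,beta,alpha,LiPF6,5,Oxalic,2.5,0.03,0.09,0.87,5A,25,93,81
18,3,beta,alpha,LiClO4,5,Formic,1.2,0.28,0.86,0.12,3A,25,71,52
19,3,beta,alpha,LiBF4,4.1,Acetic,2.4,0.1,0.98,0.01,5A,0,58,59
20,3,beta,alpha,LiNTf2,1.8,None,2.8,0.07,0.31,0.15,3A,0,51,86
21,4,beta,alpha,LiBF4,0.5,Formic,1.1,0.18,0.17,0.53,3A,25,82,80
22,4,beta,alpha,LiBF4,2.1,Formic,2.3,0.06,0.82,0.04,3A,0,62,64
23,4,beta,beta,LiOTf,4,TFA,2.5,0.21,0.38,0.49,5A,0,76,65
24,4,beta,alpha,LiPF6,4.2,Acetic,2.6,0.15,0.05,0.44,None,0,92,72
25,4,beta,alpha,LiOTf,3.1,Formic,1.7,0.05,0.13,0.23,5A,25,74,61
26,5,beta,beta,LiB(C6F5)4,2.5,TFA,1.3,0.08,0.1,0.7,5A,25,0,0
27,5,beta,beta,LiOTf,3.3,Oxalic,1,0.07,0.52,0.12,4A,25,81,49
28,5,beta,beta,LiB(C6F5)4,1.5,Formic,2.4,0.16,0.55,0.34,4A,0,0,0
29,5,beta,beta,LiBF4,4.5,Oxalic,1.4,0.26,0.55,0.38,3A,25,94,71
30,5,beta,alpha,LiClO4,3.7,Oxalic,2.3,0.23,0.12,0.56,3A,25,87,79
31,6,beta,beta,LiClO4,3.2,Oxalic,2.5,0.13,0.63,0.34,None,25,99,45
32,6,beta,beta,LiNTf2,4.2,Oxalic,2.7,0.28,0.46,0.25,4A,25,13,77
33,6,beta,beta,LiNTf2,1.2,Oxalic,2.9,0.21,0.04,0.5,4A,0,94,80
34,6,beta,alpha,LiB(C6F5)4,3,TFA,1,0.19,0.03,0.15,4A,25,12,0
35,6,beta,beta,LiPF6,4.1,Formic,2.1,0.05,0.57,0.39,5A,25,57,78
36,7,beta,alpha,LiOTf,3.6,Acetic,2.5,0.17,0.28,0.27,3A,0,95,66
37,7,beta,beta,LiPF6,3.1,Acetic,1.8,0.09,0.4,0.55,4A,0,98,77
38,7,beta,beta,LiClO4,2.5,None,1.3,0.14,0.43,0.49,3A,25,3,0
39,7,beta,alpha,LiBF4,2.5,Oxalic,2.2,0.14,0.29,0.63,4A,0,73,80
40,7,beta,alpha,LiB(C6F5)4,1.5,Formic,2.1,0.24,0.87,0.06,4A,0,33,69
41,8,beta,alpha,LiClO4,0.8,Acetic,2.5,0.27,0.13,0.71,4A,25,58,73
42,8,beta,alpha,LiBF4,2.2,Acetic,1,0.27,0.54,0.29,5A,0,68,74
43,8,beta,alpha,LiOTf,1.8,Acetic,1.9,0.16,0.09,0.47,4A,0,30,73
44,8,beta,beta,LiB(C6F5)4,1.3,None,2.9,0.24,0.21,0.62,5A,0,26,41
45,8,beta,beta,LiClO4,1.8,Oxalic,1.7,0.31,0.7,0.27,4A,25,85,50
46,9,beta,beta,LiPF6,2.7,Formic,2.5,0.2,0.13,0.48,None,25,99,41
47,9,beta,alpha,LiBF4,0.8,TFA,1.4,0.09,0.38,0.06,3A,25,58,74
48,9,beta,alpha,LiBF4,3.5,Acetic,1.4,0.21,0.11,0.73,4A,25,85,77
49,9,beta,beta,LiClO4,5,Formic,1.5,0.18,0.53,0.21,5A,25,100,36
50,9,beta,alpha,LiNTf2,3.2,Formic,1,0.22,0.33,0.31,3A,25,44,81
51,10,beta,alpha,LiPF6,2.7,Acetic,2.3,0.03,0,0.99,5A,0,50,80
52,10,beta,alpha,LiPF6,1.3,Formic,1.2,0.11,0.03,0.11,3A,0,63,80
53,10,beta,beta,LiClO4,0.8,Acetic,2.4,0.1,0.45,0.43,3A,0,56,74
54,10,beta,alpha,LiBF4,3.2,Formic,2.8,0.14,0.57,0.29,3A,0,78,76
55,10,beta,alpha,LiBF4,1.1,TFA,2.5,0.06,0.02,0.36,4A,0,73,80
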