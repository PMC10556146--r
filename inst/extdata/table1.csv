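compound,cas,model1_ug_ml,model2_ug_ml
beta-Damascenone,23696-85-7,0.07,
Furfural,98-01-1,3.07,1.53
3-Methylbutanal,590-86-3,0.36,0.68
2-Methylbutanal,96-17-3,0.23,0.09
2-Phenylethanol,60-12-8,13.90,8.90
2-Methyl-1-butanol,137-32-6,0.82,
3-Methyl-1-butanol,123-51-3,9.39,46.93
3-Methylbutyl acetate,123-92-2,2.42,0.72
2-Phenylethyl acetate,103-45-7,2.47,4.02
3-Methylbutyl octanoate,2035-99-6,0.80,0.16
3-Methylbutyl decanoate,2306-91-4,,0.31
Ethyl butanoate,105-54-4,0.30,0.30
Ethyl hexanoate,123-66-0,3.65,1.30
Ethyl heptanoate,106-30-9,0.39,
Ethyl octanoate,106-32-1,3.23,2.02
Ethyl decanoate,110-38-3,2.12,2.76
Ethyl nonanoate,123-29-5,0.20,0.59
Ethyl tetradecanoate,124-06-1,0.13,0.21
Ethyl hexadecanoate,628-97-7,0.23,
Octanoic acid,124-07-2,0.33,0.21
Decanoic acid,334-48-5,0.38,0.38
Dodecanoic acid,143-07-7,,0.16
cis/trans Whisky-lactone,39212-23-2,0.36,0.36
gamma-Nonalactone,104-61-0,0.30,0.35
2-Methoxyphenol,90-05-1,3.36,0.54
Phenol,108-95-2,,0.12
4-Methylphenol,106-44-5,0.03,0.05
4-Ethylphenol,123-07-9,0.02,
4-Allyl-2-methoxyphenol,97-53-0,,0.62
Vanillin,121-33-5,0.36,1.43
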