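component,covariate,support,estimate,se,deviance_reduction_pct
count,DogAverageAge,municipal,-0.19,0.04,20.40
count,FemaleDogRatio,municipal,0.01,0.01,3.76
count,MixedBreedRatio,municipal,0.03,0.00,20.40
count,AverageIncomeTax,municipal,0.11,0.02,21.53
count,HumanPopulationDensity,municipal,0.04,0.03,0.75
count,DistanceToVetCare,municipal,-0.04,0.11,8.76
zero_inflation,DogAverageAge,municipal,-3.61,0.61,24.41
count,DogAverageAge,refined,-0.21,0.05,13.86
count,FemaleDogRatio,refined,0.02,0.01,5.18
count,MixedBreedRatio,refined,0.02,0.01,18.39
count,AverageIncomeTax,refined,0.11,0.02,23.06
count,HumanPopulationDensity,refined,0.08,0.01,9.33
count,DistanceToVetCare,refined,-0.03,0.11,4.92
zero_inflation,DogAverageAge,refined,-3.69,0.63,25.26
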