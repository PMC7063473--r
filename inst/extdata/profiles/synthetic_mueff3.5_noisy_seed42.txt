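# synthetic noisy exponential profile: T(z) = exp(-3.5 z) * (1 + 0.01 N(0,1))
# ground truth mu_eff = 3.5 mm^-1; generated with set.seed(42)
# z_mm transmittance
0 1.01370958447147
0.0203389830508475 0.926029278233598
0.0406779661016949 0.870447201716941
0.0610169491525424 0.812815902190198
0.0813559322033898 0.755246397124769
0.101694915254237 0.699776687935808
0.122033898305085 0.662247105993338
0.142372881355932 0.606984439446789
0.16271186440678 0.577233572250132
0.183050847457627 0.52660459623359
0.203389830508475 0.497131792959796
0.223728813559322 0.46745980499011
0.244067796610169 0.419696585494215
0.264406779661017 0.395258416153417
0.284745762711864 0.368636478966441
0.305084745762712 0.345951307876594
0.325423728813559 0.319234407045387
0.345762711864407 0.290226606516264
0.366101694915254 0.270884342153528
0.386440677966102 0.261995588003006
0.406779661016949 0.240075958852744
0.427118644067797 0.220272711809395
0.447457627118644 0.208498726026291
0.467796610169491 0.196869428727111
0.488135593220339 0.18457488957264
0.508474576271186 0.167969141142869
0.528813559322034 0.156699790508162
0.549152542372881 0.143729413795207
0.569491525423729 0.136882837803536
0.589830508474576 0.126081431896053
0.610169491525424 0.118712691833696
0.630508474576271 0.110830196376837
0.650847457627119 0.103553357097516
0.671186440677966 0.0948687974617735
0.691525423728814 0.089340341727257
0.711864406779661 0.081362188730239
0.732203389830508 0.0764906027815064
0.752542372881356 0.0711870905219344
0.772881355932203 0.065250405443053
0.793220338983051 0.062292762879276
0.813559322033898 0.0581110316311467
0.833898305084746 0.0538118715899802
0.854237288135593 0.0506772862236806
0.874576271186441 0.0464996482448581
0.894915254237288 0.0430247101933449
0.915254237288135 0.0408000900738366
0.935593220338983 0.0375259231795166
0.95593220338983 0.035742137018858
0.976271186440678 0.0326708201792695
0.996610169491525 0.0307581427592779
1.01694915254237 0.028549725662491
1.03728813559322 0.0262949665080978
1.05762711864407 0.0250705733526433
1.07796610169492 0.0231335128356486
1.09830508474576 0.0214255618082811
1.11864406779661 0.0199906113770014
1.13898305084746 0.0186917924568922
1.15932203389831 0.0173055296944404
1.17966101694915 0.0156200250151818
1.2 0.0150382966626228
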