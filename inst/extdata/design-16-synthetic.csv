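"mean","group","confound"
1,-1,1.59528080213779
1,-1,0.329507771815361
1,-1,-0.820468384118015
1,-1,0.487429052428485
1,-1,0.738324705129217
1,-1,0.575781351653492
1,-1,-0.305388387156356
1,-1,1.51178116845085
1,1,0.389843236411431
1,1,-0.621240580541804
1,1,-2.2146998871775
1,1,1.12493091814311
1,1,-0.0449336090152309
1,1,-0.0161902630989461
1,1,0.943836210685299
1,1,0.821221195098089
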