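horizon,perspective,scenario,per_child_total
5,direct,NoDetention,23652
5,direct,FamilyDetention,24281
5,direct,ZeroTolerance,24887
5,societal,NoDetention,33008
5,societal,FamilyDetention,33790
5,societal,ZeroTolerance,34544
10,direct,NoDetention,49593
10,direct,FamilyDetention,50734
10,direct,ZeroTolerance,51875
10,societal,NoDetention,74139
10,societal,FamilyDetention,75644
10,societal,ZeroTolerance,77158
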