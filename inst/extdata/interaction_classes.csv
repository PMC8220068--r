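name,agent1_k,agent1_k_eps,agent1_c5,agent1_c6,agent1_c7,agent1_c8,agent1_c9,agent2_k,agent2_k_eps,agent2_c5,agent2_c6,agent2_c7,agent2_c8,agent2_c9
Avoiding,0,0,1,1,5,3,0,0,0,0.4,1,0,2.7,0
Bumping,0,0.9,1,0.8,0,0,0,0,1,0.8,10,0,1,0
Chasing,0,0,1,10,7,0,0,0,0,1,1,7,0,0
Dodging,0,0,1,0.5,7,5,0,0,0,3,1,0,0,0
Fighting,0.1,0,1,1,3,1,0,0.1,1,1,1,3,1,0
Flirting,0,0,1,1,5,0,0,0.5,1,0.6,1,2,1,0
Following,0,0,1,10,7,0,0,0,0,1,4,4,0,0
Frightening,0,0,1,1,5,0,0,0,0,1,1,5,0,0.5
Guarding,0,0,1,1,5,0,0,0,0,1,1,3,0,0.5
Meeting,0,0.2,1,2,0,6,0,0.5,1,0.22,3,0,6,0
Playing,0,0,1,1,5,0,0,0,1,1,1,10,0,0.5
Pulling,0,0,1,10,0,2.6,0,0,0,0.9,5,0,2.6,0
Pushing,0,0,1,10,0,2.5,0,0,0,0.1,1,0,0,2.5
Tug of War,0,0.2,1,10,0,6,0,0,0.5,0.9,5,0,0,0.5
Walking,0,0.2,1,10,0,1,0,0,0,0.22,10,0,0,0
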