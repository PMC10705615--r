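standard,appropriate_feed,appropriate_water,nutrition,environmental_comfort,resting_comfort,ease_of_movement,physical_environment,absence_of_injuries,absence_of_disease,mutilations,fitness,health,environmental_enrichment,social_behaviour,human_animal_relationship,behavioural_interactions,final_score
1,45,55,46,50,45,55,48,100,100,0,35,19,65,100,35,49,47
2,25,45,28,20,5,5,6,25,35,0,5,4,5,5,35,9,7.5
3,5,30,8,20,5,5,6,25,15,0,5,3,5,5,35,9,7
4,45,45,45,50,15,55,29,100,35,0,55,13,5,10,35,10,21
5,25,30,26,50,5,5,6,40,35,0,5,5,5,10,5,6,6
6,35,45,36,50,15,55,29,100,35,0,55,13,15,5,35,10,21
7,45,100,53,50,5,30,16,40,35,0,5,5,5,10,35,10,13
8,45,45,45,50,15,55,29,100,35,0,55,13,5,10,35,10,21
9,45,30,31,5,5,15,6,100,35,0,55,13,5,65,35,19,16
10,45,30,31,50,15,55,29,100,35,2,5,7,5,10,35,10,19.5
11,45,30,31,20,5,55,15,100,35,17,5,14,5,10,35,10,14.5
12,45,30,31,50,5,55,23,25,35,0,5,4,5,65,35,19,21
13,5,5,5,5,5,5,5,5,35,0,5,3,5,5,35,9,5
14,25,45,28,20,5,20,12,25,45,100,35,32,60,10,35,18,23
15,25,15,15,50,5,20,11,25,15,0,5,3,5,5,35,9,10
16,45,5,7,100,5,5,12,100,5,0,5,2,5,5,5,5,6
17,45,5,7,100,45,55,51,100,35,17,55,25,15,20,35,18,21.5
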