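item_id,context,interdependence_response,n_matsigenka,n_mestizo,atalaya_only
1,spousal_relations,Okay (role-reversed household division of labor),71,80,FALSE
2,parent_offspring,Okay (daughter must care for sibling instead of playing),77,78,FALSE
3,inheritance,Not okay (son wears deceased father's hat),74,79,FALSE
4,education,Okay (teacher hits students who do not learn),75,74,FALSE
5,education,Okay (student never asks the teacher questions),79,81,FALSE
6,healthcare,Health post first for respiratory illness,79,81,FALSE
7,inheritance,Both pots to the daughter who has none,76,82,FALSE
8,religion,Hell or somewhere else (good person unbaptized),64,60,FALSE
9,religion,Heaven (bad person baptized),64,29,TRUE
10,wage_labor,Okay (hired man pauses work to visit a friend),75,77,FALSE
11,commerce,Cheap store with mean owner,63,77,FALSE
12,spousal_relations,Okay (cross-cousin marriage),70,30,TRUE
13,parent_offspring,Obey parents and marry him anyway,63,81,FALSE
14,wage_labor,Okay to go and become drunk,67,80,FALSE
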