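type,from,to,km
unit,Italy,,
unit,Sicily,,
unit,Sardinia,,
unit,Corsica,,
unit,France,,
unit,Spain,,
unit,Balearics,,
unit,Tunisia,,
unit,Morocco,,
unit,Malta,,
unit,Elba,,
unit,Pianosa,,
unit,Ischia,,
unit,Levant,,
unit,Levanzo,,
unit,Capraia,,
merge,Elba,Italy,
merge,Pianosa,Italy,
merge,Ischia,Italy,
merge,Levant,France,
merge,Levanzo,Sicily,
distance,Italy,Sicily,3
distance,Sardinia,Corsica,5
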