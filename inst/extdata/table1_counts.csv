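drug,date,kind,count
alcohol,2014-06-20,base,389000000
cannabis,2014-06-20,base,59100000
cocaine,2014-06-20,base,58600000
lsd,2014-06-20,base,48600000
heroin,2014-06-20,base,46800000
ecstasy,2014-06-20,base,42900000
ghb,2014-06-20,base,23500000
methadone,2014-06-20,base,13400000
butane,2014-06-20,base,11800000
khat,2014-06-20,base,10600000
amphetamine,2014-06-20,base,9070000
methamphetamine,2014-06-20,base,8780000
ketamine,2014-06-20,base,8400000
buprenorphine,2014-06-20,base,6400000
benzodiazepines,2014-06-20,base,4520000
mephedrone,2014-06-20,base,2050000
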