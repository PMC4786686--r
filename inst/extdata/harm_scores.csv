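drug,harm_score
alcohol,72
cocaine,27
heroin,55
benzodiazepines,15
khat,9
buprenorphine,7
methamphetamine,33
amphetamine,23
ketamine,15
cannabis,20
mephedrone,13
methadone,14
butane,11
ecstasy,9
ghb,19
lsd,7
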