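drug,date,kind,count
alcohol,2014-06-20,harm,107000000
cocaine,2014-06-20,harm,15000000
heroin,2014-06-20,harm,11700000
benzodiazepines,2014-06-20,harm,467000
khat,2014-06-20,harm,711000
buprenorphine,2014-06-20,harm,374000
methamphetamine,2014-06-20,harm,513000
amphetamine,2014-06-20,harm,465000
ketamine,2014-06-20,harm,411000
cannabis,2014-06-20,harm,2710000
mephedrone,2014-06-20,harm,92000
methadone,2014-06-20,harm,543000
butane,2014-06-20,harm,386000
ecstasy,2014-06-20,harm,669000
ghb,2014-06-20,harm,291000
lsd,2014-06-20,harm,580000
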