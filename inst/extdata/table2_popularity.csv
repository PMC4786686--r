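drug,date,index_percent
alcohol,2012-05-01,100
alcohol,2012-10-01,100
alcohol,2013-01-01,100
alcohol,2013-07-01,100
alcohol,2014-02-01,100
alcohol,2014-06-20,100
cannabis,2012-05-01,6.3
cannabis,2012-10-01,5.9
cannabis,2013-01-01,6.9
cannabis,2013-07-01,7.7
cannabis,2014-02-01,10.1
cannabis,2014-06-20,15.2
cocaine,2012-05-01,10.5
cocaine,2012-10-01,9.4
cocaine,2013-01-01,10.3
cocaine,2013-07-01,10.4
cocaine,2014-02-01,11.4
cocaine,2014-06-20,15.1
lsd,2012-05-01,6.4
lsd,2012-10-01,6.8
lsd,2013-01-01,7.9
lsd,2013-07-01,8.8
lsd,2014-02-01,8.8
lsd,2014-06-20,12.5
heroin,2012-05-01,8.8
heroin,2012-10-01,9.1
heroin,2013-01-01,10.0
heroin,2013-07-01,10.4
heroin,2014-02-01,11.0
heroin,2014-06-20,12.0
ecstasy,2012-05-01,6.2
ecstasy,2012-10-01,5.1
ecstasy,2013-01-01,5.6
ecstasy,2013-07-01,6.1
ecstasy,2014-02-01,6.6
ecstasy,2014-06-20,11.0
ghb,2012-05-01,0.9
ghb,2012-10-01,1.1
ghb,2013-01-01,1.3
ghb,2013-07-01,1.5
ghb,2014-02-01,1.7
ghb,2014-06-20,6.0
methadone,2012-05-01,1.8
methadone,2012-10-01,2.1
methadone,2013-01-01,2.2
methadone,2013-07-01,2.0
methadone,2014-02-01,1.7
methadone,2014-06-20,3.4
butane,2012-05-01,1.8
butane,2012-10-01,2.1
butane,2013-01-01,2.3
butane,2013-07-01,2.3
butane,2014-02-01,2.2
butane,2014-06-20,3.0
khat,2012-05-01,1.3
khat,2012-10-01,1.2
khat,2013-01-01,1.3
khat,2013-07-01,1.4
khat,2014-02-01,1.6
khat,2014-06-20,2.7
amphetamine,2012-05-01,1.2
amphetamine,2012-10-01,1.5
amphetamine,2013-01-01,2.2
amphetamine,2013-07-01,1.6
amphetamine,2014-02-01,1.6
amphetamine,2014-06-20,2.3
methamphetamine,2012-05-01,1.5
methamphetamine,2012-10-01,1.6
methamphetamine,2013-01-01,1.6
methamphetamine,2013-07-01,1.6
methamphetamine,2014-02-01,1.6
methamphetamine,2014-06-20,2.3
ketamine,2012-05-01,2.6
ketamine,2012-10-01,2.3
ketamine,2013-01-01,2.2
ketamine,2013-07-01,1.9
ketamine,2014-02-01,1.6
ketamine,2014-06-20,2.2
buprenorphine,2012-05-01,1.0
buprenorphine,2012-10-01,0.6
buprenorphine,2013-01-01,0.6
buprenorphine,2013-07-01,0.6
buprenorphine,2014-02-01,0.5
buprenorphine,2014-06-20,1.6
benzodiazepines,2012-05-01,1.7
benzodiazepines,2012-10-01,1.3
benzodiazepines,2013-01-01,1.3
benzodiazepines,2013-07-01,1.2
benzodiazepines,2014-02-01,1.0
benzodiazepines,2014-06-20,1.2
mephedrone,2012-05-01,0.1
mephedrone,2012-10-01,0.1
mephedrone,2013-01-01,0.1
mephedrone,2013-07-01,0.1
mephedrone,2014-02-01,0.1
mephedrone,2014-06-20,0.5
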