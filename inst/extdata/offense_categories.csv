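label,category
HOMICIDE,violent
ASSAULT,violent
AGGRAVATED ASSAULT,violent
ROBBERY,violent
RAPE,violent
KIDNAPPING,violent
BURGLARY,property
BREAKING AND ENTERING,property
ARSON,property
VANDALISM,property
TRESPASSING,property
DRUG VIOLATION,vice
NARCOTICS POSSESSION,vice
PROSTITUTION,vice
GAMBLING,vice
LIQUOR LAW VIOLATION,vice
LARCENY,theft
THEFT,theft
SHOPLIFTING,theft
PICKPOCKETING,theft
STOLEN PROPERTY,theft
MOTOR VEHICLE THEFT,vehicular
DRIVING WHILE IMPAIRED,vehicular
HIT AND RUN,vehicular
RECKLESS DRIVING,vehicular
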