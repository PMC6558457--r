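[
  {
    "arm": "lobectomy",
    "age": 45,
    "life_expectancy": 12.5817729496172,
    "os5": 0.8896789466481
  },
  {
    "arm": "lobectomy",
    "age": 50,
    "life_expectancy": 12.429316842658,
    "os5": 0.882579920456171
  },
  {
    "arm": "lobectomy",
    "age": 55,
    "life_expectancy": 12.2057643657358,
    "os5": 0.872549206392948
  },
  {
    "arm": "lobectomy",
    "age": 60,
    "life_expectancy": 11.8714090509668,
    "os5": 0.85803464817348
  },
  {
    "arm": "lobectomy",
    "age": 65,
    "life_expectancy": 11.3639983901039,
    "os5": 0.836480697211019
  },
  {
    "arm": "lobectomy",
    "age": 70,
    "life_expectancy": 10.5923923493599,
    "os5": 0.803635456771173
  },
  {
    "arm": "lobectomy",
    "age": 75,
    "life_expectancy": 9.44845119682602,
    "os5": 0.752480070351027
  },
  {
    "arm": "lobectomy",
    "age": 80,
    "life_expectancy": 7.93629686577727,
    "os5": 0.671966117831962
  },
  {
    "arm": "lobectomy",
    "age": 85,
    "life_expectancy": 6.22855727966152,
    "os5": 0.547137227018197
  }
]
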