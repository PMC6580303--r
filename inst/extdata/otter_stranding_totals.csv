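period,bin,shark_total,nonshark_total
1997-1999,0,4,12
2000-2002,1,4,30
2003-2005,2,7,48
2006-2008,3,7,58
2009-2011,4,23,39
2012-2014,5,33,49
2015-2017,6,47,70
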