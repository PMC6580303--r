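period,bin,sex,maturity,cause,count
1997-1999,0,M,mature,shark,0
1997-1999,0,M,mature,other,3
1997-1999,0,M,immature,shark,0
1997-1999,0,M,immature,other,3
1997-1999,0,F,mature,shark,2
1997-1999,0,F,mature,other,3
1997-1999,0,F,immature,shark,2
1997-1999,0,F,immature,other,3
2000-2002,1,M,mature,shark,2
2000-2002,1,M,mature,other,5
2000-2002,1,M,immature,shark,1
2000-2002,1,M,immature,other,7
2000-2002,1,F,mature,shark,1
2000-2002,1,F,mature,other,10
2000-2002,1,F,immature,shark,1
2000-2002,1,F,immature,other,8
2003-2005,2,M,mature,shark,4
2003-2005,2,M,mature,other,12
2003-2005,2,M,immature,shark,1
2003-2005,2,M,immature,other,8
2003-2005,2,F,mature,shark,1
2003-2005,2,F,mature,other,21
2003-2005,2,F,immature,shark,1
2003-2005,2,F,immature,other,7
2006-2008,3,M,mature,shark,4
2006-2008,3,M,mature,other,9
2006-2008,3,M,immature,shark,2
2006-2008,3,M,immature,other,17
2006-2008,3,F,mature,shark,7
2006-2008,3,F,mature,other,13
2006-2008,3,F,immature,shark,0
2006-2008,3,F,immature,other,19
2009-2011,4,M,mature,shark,9
2009-2011,4,M,mature,other,10
2009-2011,4,M,immature,shark,3
2009-2011,4,M,immature,other,9
2009-2011,4,F,mature,shark,3
2009-2011,4,F,mature,other,14
2009-2011,4,F,immature,shark,4
2009-2011,4,F,immature,other,6
2012-2014,5,M,mature,shark,19
2012-2014,5,M,mature,other,13
2012-2014,5,M,immature,shark,4
2012-2014,5,M,immature,other,10
2012-2014,5,F,mature,shark,1
2012-2014,5,F,mature,other,17
2012-2014,5,F,immature,shark,7
2012-2014,5,F,immature,other,9
2015-2017,6,M,mature,shark,20
2015-2017,6,M,mature,other,15
2015-2017,6,M,immature,shark,17
2015-2017,6,M,immature,other,17
2015-2017,6,F,mature,shark,1
2015-2017,6,F,mature,other,15
2015-2017,6,F,immature,shark,9
2015-2017,6,F,immature,other,23
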