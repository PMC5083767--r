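patient_id,fill_date,atc_code,units_total,units_per_day,total_ddd,formulation,prescriber
P00001,1996-09-30,N06AB05,30,1,30,solid,specialist
P00001,1996-11-09,N06AB05,30,1,60,solid,specialist
P00001,1996-12-14,N06AB05,30,1,60,solid,specialist
P00002,2007-03-24,N06AB03,30,1,30,solid,GP
P00002,2007-04-26,N06AB03,30,1,30,solid,GP
P00002,2007-05-22,N06AB03,30,1,30,solid,GP
P00002,2007-07-02,N02BA01,20,2,10,solid,GP
P00003,2013-04-01,N06AB04,30,1,15,solid,specialist
P00003,2013-04-27,N06AB04,30,1,15,solid,specialist
P00003,2013-05-27,N06AB04,30,1,15,solid,specialist
P00004,1995-09-18,N06AX05,30,1,5,solid,GP
P00005,1999-05-24,N06AA09,30,1,3,solid,GP
P00005,1999-07-23,N06AA09,30,1,3,solid,GP
P00005,2000-02-06,H01BA02,30,1,30,solid,GP
P00006,2002-05-08,N06AA10,30,1,10,solid,GP
P00006,2002-05-30,N06AA10,30,1,20,solid,GP
P00006,2002-06-30,N06AA10,30,1,20,solid,GP
P00006,2002-08-01,N06AA10,30,1,20,solid,GP
P00007,2013-09-06,N06AB04,30,1,15,solid,specialist
P00007,2013-10-08,N06AB04,30,1,15,solid,specialist
P00008,2002-04-05,N06AB05,30,1,30,solid,GP
P00008,2002-05-06,N06AB05,30,1,30,solid,GP
P00009,2007-04-22,N06AB04,30,1,30,solid,GP
P00009,2007-05-27,N06AB04,30,1,30,solid,GP
P00010,2007-05-30,N06AB04,25,1,25,solid,GP
P00010,2007-06-19,N06AB04,25,1,25,solid,GP
P00011,2012-09-16,N06AB04,30,1,15,solid,GP
P00011,2012-10-15,N06AB04,30,1,15,solid,GP
P00012,1996-11-29,N06AX11,30,1,15,solid,GP
P00012,1997-03-04,N02BE01,20,2,10,solid,GP
P00013,1998-12-21,N06AB05,30,1,15,solid,GP
P00013,1999-01-21,N06AB05,30,1,15,solid,GP
P00014,1995-12-15,N06AA09,30,1,10,solid,GP
P00014,1996-01-14,N06AA09,30,1,10,solid,GP
P00014,1996-02-09,N06AA09,30,1,10,solid,GP
P00015,2004-07-17,N06AB04,30,1,7.5,solid,specialist
P00016,2000-09-29,N06AB05,25,1,25,solid,GP
P00016,2000-10-16,N06AB05,25,1,25,solid,GP
P00017,2011-09-29,N06AB04,30,1,15,solid,specialist
P00018,2001-05-29,N06AB03,30,1,15,solid,GP
P00018,2001-07-05,N06AB03,30,1,7.5,solid,GP
P00018,2001-07-30,N06AB03,30,1,7.5,solid,GP
P00019,1995-08-31,N06AA09,30,1,6,solid,GP
P00019,1995-09-25,N06AA09,30,1,10,solid,GP
P00019,1995-10-17,N06AA09,30,1,6,solid,GP
P00020,2008-06-04,N06AB04,30,1,30,solid,specialist
P00020,2008-07-11,N06AB04,30,1,60,solid,specialist
P00020,2008-08-07,N06AB04,30,1,60,solid,specialist
P00021,1997-07-09,N06AB08,30,1,15,solid,GP
P00021,1997-08-06,N06AB08,30,1,30,solid,GP
P00021,1997-09-10,N06AB08,30,1,30,solid,GP
P00022,2002-07-11,N06AB04,30,1,7.5,solid,specialist
P00022,2002-08-11,N06AB04,30,1,7.5,solid,specialist
P00022,2002-09-13,N06AB04,30,1,7.5,solid,specialist
P00023,2011-07-24,N06AX11,30,1,30,solid,specialist
P00023,2011-08-23,N06AX11,30,1,30,solid,specialist
P00024,1997-03-10,N06AX03,30,1,7.5,solid,specialist
P00024,1997-03-30,N06AX03,30,1,15,solid,specialist
P00024,1997-04-26,N06AX03,30,1,15,solid,specialist
P00024,1997-05-24,N06AX03,30,1,15,solid,specialist
P00025,2001-10-03,N06AA04,30,0,10,solid,GP
P00026,2013-04-29,N06AB06,30,1,30,solid,GP
P00026,2013-05-29,N06AB06,30,1,30,solid,GP
P00027,2013-03-24,N06AB04,30,1,15,solid,specialist
P00027,2013-04-26,N06AB04,30,1,30,solid,specialist
P00027,2013-05-31,N06AB04,30,1,30,solid,specialist
P00028,2000-08-23,N06AX03,30,1,7.5,solid,GP
P00028,2000-09-23,N06AX03,30,1,15,solid,GP
P00028,2000-10-20,N06AX03,30,1,15,solid,GP
P00029,2012-08-12,N06AX11,30,1,15,solid,specialist
P00029,2012-11-18,N06AX11,30,1,15,solid,specialist
P00030,2008-09-17,N02BE01,20,2,10,solid,specialist
P00030,2008-09-18,N06AB03,30,1,15,solid,specialist
P00030,2008-10-25,N06AB03,30,1,30,solid,specialist
P00030,2008-11-23,N06AB03,30,1,30,solid,specialist
P00030,2008-12-23,N06AB03,30,1,30,solid,specialist
P00031,2006-08-19,N06AB03,30,1,30,solid,specialist
P00031,2006-09-24,N06AB03,30,1,30,solid,specialist
P00031,2006-10-27,N06AB03,30,1,30,solid,specialist
P00032,2001-06-11,N06AA02,25,1,12.5,solid,GP
P00032,2001-06-29,N06AA02,25,1,12.5,solid,GP
P00033,2001-06-23,N06AB06,25,1,12.5,solid,GP
P00033,2001-07-23,N06AB06,25,1,12.5,solid,GP
P00034,2011-04-21,N06AB04,30,1,30,solid,specialist
P00035,2005-09-12,N06AB04,30,1,30,solid,GP
P00035,2005-10-09,N06AB04,30,1,60,solid,GP
P00035,2005-11-07,N06AB04,30,1,60,solid,GP
P00035,2005-11-13,N02BA01,20,2,10,solid,GP
P00036,1999-01-26,N06AX16,30,1,30,solid,specialist
P00036,1999-02-16,N06AX16,30,1,22.5,solid,specialist
P00036,1999-03-13,N06AX16,30,1,30,solid,specialist
P00036,1999-06-25,N02BA01,20,2,10,solid,specialist
P00037,2012-07-28,N06AB03,30,1,30,solid,specialist
P00037,2012-09-01,N06AB03,30,1,30,solid,specialist
P00037,2012-10-05,N06AB03,30,1,30,solid,specialist
P00037,2012-10-21,M01AE01,20,2,10,solid,specialist
P00038,2011-05-08,M01AE01,20,2,10,solid,specialist
P00038,2011-07-05,N06AB03,30,1,15,solid,specialist
P00038,2011-07-25,N06AB03,30,1,30,solid,specialist
P00038,2011-08-14,N06AB03,30,1,15,solid,specialist
P00039,2004-08-27,N06AB04,30,1,30,solid,GP
P00039,2004-09-25,N06AB04,30,1,15,solid,GP
P00039,2004-10-24,N06AB04,30,1,30,solid,GP
P00040,2012-11-02,N06AB06,30,1,30,solid,specialist
P00040,2012-12-20,N06AB06,30,1,30,solid,specialist
P00041,1999-11-03,N06AA02,30,1,6,solid,GP
P00041,1999-11-29,N06AA02,30,1,6,solid,GP
P00042,2004-10-21,N06AB06,30,1,30,solid,specialist
P00042,2004-11-22,N06AB06,30,1,30,solid,specialist
P00042,2004-12-24,N06AB06,30,1,30,solid,specialist
P00043,2002-06-21,N06AA10,30,1,10,solid,specialist
P00043,2002-07-15,N06AA10,30,1,20,solid,specialist
P00043,2002-08-13,N06AA10,30,1,20,solid,specialist
P00043,2002-09-12,N06AA10,30,1,20,solid,specialist
P00044,1996-06-06,N02BA01,20,2,10,solid,GP
P00044,1996-10-18,N06AB05,30,1,30,solid,GP
P00045,1995-05-05,N06AB08,30,1,7.5,solid,GP
P00045,1995-06-02,N06AB08,30,1,7.5,solid,GP
P00045,1995-07-03,N06AB08,30,1,7.5,solid,GP
P00046,2002-08-24,N06AB08,30,1,30,solid,GP
P00047,1995-02-02,N06AB05,30,0,15,solid,GP
P00048,2008-05-27,N06AB10,30,1,15,solid,specialist
P00048,2008-06-21,N02BA01,20,2,10,solid,specialist
P00048,2008-07-02,N06AB10,30,1,30,solid,specialist
P00048,2008-08-07,N06AB10,30,1,30,solid,specialist
P00049,1998-07-01,N06AB08,30,0,15,solid,GP
P00050,2006-06-27,N06AX11,30,1,15,solid,specialist
P00050,2006-07-25,N06AX11,30,1,15,solid,specialist
P00050,2006-08-27,N06AX11,30,1,15,solid,specialist
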